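#' Read / write count tables
#'
#' Count tables are tab-separated with samples as rows; the first column
#' holds sample identifiers and the header the ASV identifiers.
#'
#' @param path File path.
#' @return Integer matrix with sample rownames.
#' @export
read_count_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_count_table
#' @param counts Count matrix.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample metadata
#'
#' @param path File path.
#' @return Data frame with rownames set to `sample_id`.
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(df) <- df$sample_id
  df
}

#' @rdname read_metadata
#' @param metadata Data frame with a `sample_id` column.
#' @export
write_metadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trait-labelled reference phylogeny from files
#'
#' @param tree_path Newick tree file.
#' @param alignment_path FASTA file of the aligned reference sequences.
#' @param trait_path Tab-separated table with columns `tip_id`, `trait`
#'   (`producer` / `nonproducer`) and optionally `genus`.
#' @return A [reference_phylogeny()].
#' @export
read_reference_phylogeny <- function(tree_path, alignment_path, trait_path) {
  tree <- ape::read.tree(tree_path)
  aln <- Biostrings::readDNAStringSet(alignment_path)
  tt <- read.delim(trait_path, stringsAsFactors = FALSE)
  traits <- setNames(tt$trait, tt$tip_id)
  genus <- if ("genus" %in% names(tt)) setNames(tt$genus, tt$tip_id) else NULL
  reference_phylogeny(tree, aln, traits, genus)
}

#' Write a reference phylogeny to files
#'
#' @param ref A [reference_phylogeny()].
#' @param tree_path,alignment_path,trait_path Output files (Newick, FASTA,
#'   TSV).
#' @export
write_reference_phylogeny <- function(ref, tree_path, alignment_path,
                                      trait_path) {
  ape::write.tree(ref$tree, tree_path)
  seqs <- Biostrings::DNAStringSet(apply(ref$alignment, 1, paste,
                                         collapse = ""))
  Biostrings::writeXStringSet(seqs, alignment_path)
  write.table(data.frame(tip_id = names(ref$traits),
                         trait = unname(ref$traits),
                         genus = unname(ref$genus)),
              trait_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tree_path)
}

#' Write edge records as a tab-separated edge list
#'
#' @param edges Edge records from [build_network()].
#' @param path Output file.
#' @export
write_edge_list <- function(edges, path) {
  out <- edges
  for (col in c("mic_e", "tic_e", "rho"))
    out[[col]] <- round(out[[col]], 6)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write screening results
#'
#' @param screen Data frame from [screen_queries()].
#' @param path Output file.
#' @export
write_screen_results <- function(screen, path) {
  screen$identity <- round(screen$identity, 4)
  write.table(screen, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
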