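# Independent oracles used across the suite. Each is a direct, enumerative
# implementation kept free of the package's computational paths.

## ---- MICe / TICe: exhaustive maximisation over all cut subsets -----------

# adaptive mass equipartition of tie-blocks (definitional, shared with the
# estimator; the searched quantity is the partition of the other axis)
oracle_equip_rows <- function(v, l) {
  o <- order(v)
  sizes <- rle(v[o])$lengths
  n <- sum(sizes)
  bin <- integer(length(sizes))
  curr <- 0L; before <- 0; cnt <- 0
  for (b in seq_along(sizes)) {
    desired <- (n - before) / (l - curr)
    if (cnt > 0 && curr < l - 1 &&
        abs(cnt + sizes[b] - desired) > abs(cnt - desired)) {
      curr <- curr + 1L; before <- before + cnt; cnt <- 0
    }
    bin[b] <- curr; cnt <- cnt + sizes[b]
  }
  out <- integer(length(v))
  out[o] <- rep(bin, sizes)
  out
}

oracle_mi <- function(cx, cy) {
  tab <- table(cx, cy)
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  s <- 0
  for (i in seq_along(px)) for (j in seq_along(py))
    if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (px[i] * py[j]))
  s
}

# best normalised MI with u optimised into <= k bins (all cut subsets at
# positions between distinct sorted u values) and v equipartitioned into l
oracle_best_orientation <- function(u, v, k, l) {
  rows <- oracle_equip_rows(v, l)
  o <- order(u)
  us <- u[o]; rs <- rows[o]
  n <- length(u)
  bounds <- which(diff(us) != 0)
  best <- 0
  for (nc in 0:(k - 1)) {
    if (nc > length(bounds)) break
    combs <- if (nc == 0) list(integer(0)) else asplit(combn(bounds, nc), 2)
    for (cc in combs) {
      col <- findInterval(seq_len(n), c(cc) + 0.5)
      val <- oracle_mi(col, rs) / log(min(k, l))
      if (val > best) best <- val
    }
  }
  best
}

oracle_mine <- function(x, y, alpha = 0.6) {
  n <- length(x)
  B <- max(4, floor(n^alpha))
  mic <- 0; tic <- 0
  for (k in 2:(B %/% 2)) for (l in 2:(B %/% k)) {
    e <- max(oracle_best_orientation(x, y, k, l),
             oracle_best_orientation(y, x, k, l))
    tic <- tic + e
    if (e > mic) mic <- e
  }
  list(mic = mic, tic = tic)
}

## ---- pairwise alignment: exhaustive enumeration of global alignments -----

# maximal score and the identity (matching cols / cols, terminal gaps
# excluded) over ALL optimal global alignments of two short sequences
oracle_global_alignment <- function(a, b, scoring = screen_scoring()) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- new.env()
  best$score <- -Inf; best$identities <- numeric(0)
  rec <- function(i, j, cols_a, cols_b, score, gap_state) {
    if (i > length(av) && j > length(bv)) {
      if (score > best$score + 1e-9) {
        best$score <- score
        best$identities <- oracle_identity_of(cols_a, cols_b)
      } else if (abs(score - best$score) <= 1e-9) {
        best$identities <- c(best$identities,
                             oracle_identity_of(cols_a, cols_b))
      }
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j] && av[i] != "N") scoring$match else
        scoring$mismatch
      rec(i + 1, j + 1, c(cols_a, av[i]), c(cols_b, bv[j]), score + s, 0L)
    }
    if (i <= length(av)) {
      pen <- if (gap_state == 1L) scoring$gap_extend else
        scoring$gap_open + scoring$gap_extend
      rec(i + 1, j, c(cols_a, av[i]), c(cols_b, "-"), score + pen, 1L)
    }
    if (j <= length(bv)) {
      pen <- if (gap_state == 2L) scoring$gap_extend else
        scoring$gap_open + scoring$gap_extend
      rec(i, j + 1, c(cols_a, "-"), c(cols_b, bv[j]), score + pen, 2L)
    }
  }
  rec(1L, 1L, character(0), character(0), 0, 0L)
  list(score = best$score, identities = unique(round(best$identities, 12)))
}

oracle_identity_of <- function(cols_a, cols_b) {
  gap <- cols_a == "-" | cols_b == "-"
  w <- length(cols_a)
  lead <- 0L
  while (lead < w && gap[lead + 1L]) lead <- lead + 1L
  trail <- 0L
  while (trail < w - lead && gap[w - trail]) trail <- trail + 1L
  idx <- seq.int(lead + 1L, w - trail)
  m <- sum(cols_a[idx] == cols_b[idx] & cols_a[idx] != "-" &
             cols_a[idx] != "N")
  m / length(idx)
}

## ---- placement: direct ancestral-state-sum likelihood --------------------

# Jukes-Cantor log-likelihood of a tree by summation over all internal node
# state assignments (vectorised over alignment columns)
oracle_tree_ll <- function(tree, seqs) {
  states <- c("A", "C", "G", "T")
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  L <- ncol(seqs)
  Pe <- function(t) {
    e <- exp(-4 * t / 3)
    m <- matrix(0.25 - 0.25 * e, 4, 4)
    diag(m) <- 0.25 + 0.75 * e
    m
  }
  Plist <- lapply(tree$edge.length, Pe)
  tipstate <- matrix(match(seqs[tree$tip.label, , drop = FALSE], states),
                     ntip, L)
  is_tip_edge <- tree$edge[, 2] <= ntip
  combos <- as.matrix(expand.grid(rep(list(1:4), nint)))
  acc <- numeric(L)
  for (r in seq_len(nrow(combos))) {
    st <- combos[r, ]
    pr <- 0.25
    for (e in which(!is_tip_edge))
      pr <- pr * Plist[[e]][st[tree$edge[e, 1] - ntip],
                            st[tree$edge[e, 2] - ntip]]
    v <- rep(pr, L)
    for (e in which(is_tip_edge)) {
      ts <- tipstate[tree$edge[e, 2], ]
      pe <- Plist[[e]][st[tree$edge[e, 1] - ntip], ]
      contrib <- ifelse(is.na(ts), 1, pe[ifelse(is.na(ts), 1, ts)])
      v <- v * contrib
    }
    acc <- acc + v
  }
  sum(log(acc))
}

# oracle attachment log-likelihood: graft a pendant tip mid-edge with
# ape::bind.tree and evaluate the extended tree directly
oracle_attachment_ll <- function(ref, query_chars, edge, pendant_grid) {
  tree <- ref$tree
  te <- tree$edge.length[edge]
  v <- tree$edge[edge, 2]
  seqs <- rbind(ref$alignment,
                ..query.. = query_chars)
  max(vapply(pendant_grid, function(pend) {
    qt <- ape::read.tree(text = sprintf("(..query..:%.10f);", pend))
    ext <- ape::bind.tree(tree, qt, where = v, position = te / 2)
    oracle_tree_ll(ext, seqs)
  }, numeric(1)))
}

## ---- ANOSIM: direct exhaustive permutation test --------------------------

oracle_anosim <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  rk <- rank(as.dist(d))
  stat <- function(g) {
    within <- as.dist(outer(g, g, "==")) == 1
    (mean(rk[!within]) - mean(rk[within])) / (n * (n - 1) / 4)
  }
  r_obs <- stat(groups)
  # enumerate assignments of positions to the first group
  g1 <- sort(unique(groups))[1]
  k <- sum(groups == g1)
  combos <- combn(n, k)
  r_all <- apply(combos, 2, function(ix) {
    g <- rep(setdiff(unique(groups), g1)[1], n)
    g[ix] <- g1
    stat(g)
  })
  list(R = r_obs, p = mean(r_all >= r_obs - 1e-12), n_perm = ncol(combos))
}
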