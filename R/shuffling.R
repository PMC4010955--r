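#' Exchangeability blocks
#'
#' Exchangeability blocks (EBs) restrict the set of permitted permutations.
#' In \code{"within_block"} mode observations are permuted only within their
#' block (blocks may differ in size); in \code{"whole_block"} mode entire
#' blocks are exchanged, keeping the within-block order intact, which
#' requires all blocks to have the same size. \code{"unrestricted"} means no
#' block structure (a single implicit block covering all observations).
#'
#' @param block_of Vector of block labels, one per observation; \code{NULL}
#'   for unrestricted exchangeability.
#' @param mode \code{"unrestricted"}, \code{"within_block"} or
#'   \code{"whole_block"}.
#' @param N Number of observations (required when \code{block_of} is NULL).
#' @return Object of class \code{"exchangeability_blocks"}.
#' @export
exchangeability_blocks <- function(block_of = NULL,
                                   mode = c("unrestricted", "within_block", "whole_block"),
                                   N = NULL) {
  mode <- match.arg(mode)
  if (is.null(block_of)) {
    if (mode != "unrestricted") stop("block labels required for ", mode, " mode")
    if (is.null(N)) stop("N required when block_of is NULL")
    block_of <- rep(1L, N)
  }
  if (anyNA(block_of)) stop("block labels contain NA")
  f <- factor(block_of, levels = unique(block_of))
  id <- as.integer(f)
  sizes <- tabulate(id)
  if (mode == "whole_block" && length(unique(sizes)) != 1L)
    stop("whole-block shuffling requires all blocks to have equal size")
  members <- split(seq_along(id), id)
  structure(list(block_of = id, mode = mode, B = nlevels(f),
                 sizes = sizes, members = members, N = length(id)),
            class = "exchangeability_blocks")
}

as_blocks <- function(blocks, N) {
  if (is.null(blocks)) return(exchangeability_blocks(N = N))
  if (!inherits(blocks, "exchangeability_blocks")) stop("not an exchangeability_blocks object")
  if (blocks$N != N) stop("block vector has wrong length")
  blocks
}

# integer class id per row, by exact row equality
row_classes <- function(X) {
  if (is.null(X)) return(NULL)
  X <- as.matrix(X)
  if (ncol(X) == 0L) return(rep(1L, nrow(X)))
  key <- apply(X, 1L, function(v) paste(sprintf("%.17g", v), collapse = "\r"))
  as.integer(factor(key, levels = unique(key)))
}

log_multiset_perms <- function(cls) {
  lfactorial(length(cls)) - sum(lfactorial(tabulate(cls)))
}

#' Maximum number of unique shufflings
#'
#' Counts the distinct permutations and/or sign flips available under a
#' block structure, accounting for repeated rows of the shuffled design
#' partition (permutations that do not alter the model are not counted).
#' Unrestricted: \code{N!/prod(N_m!)} permutations and \code{2^N} sign
#' flips; within-block: product of per-block permutation counts and
#' \code{2^N} flips; whole-block: \code{B!/prod(N_mtilde!)} permutations of
#' the \code{B} blocks and \code{2^B} flips. For the combined regime the two
#' counts multiply. Counts that overflow double precision are returned as
#' \code{Inf}.
#'
#' @param blocks Exchangeability blocks (or \code{NULL} for unrestricted).
#' @param X_rows Matrix whose repeated rows define synonymous permutations
#'   (the regressors of interest for residual-shuffling methods, the full
#'   design for Manly/ter Braak); \code{NULL} treats all rows as distinct.
#' @param regime \code{"ee"} (permutations), \code{"ise"} (sign flips) or
#'   \code{"both"}.
#' @param N Number of observations when \code{blocks} is NULL and
#'   \code{X_rows} is NULL.
#' @return Number of unique shufflings (possibly \code{Inf}).
#' @export
count_max_shufflings <- function(blocks = NULL, X_rows = NULL,
                                 regime = c("ee", "ise", "both"), N = NULL) {
  regime <- match.arg(regime)
  if (is.null(N)) N <- if (!is.null(X_rows)) nrow(as.matrix(X_rows)) else
    if (!is.null(blocks)) blocks$N else stop("cannot determine N")
  blocks <- as_blocks(blocks, N)
  cls <- if (is.null(X_rows)) seq_len(N) else row_classes(X_rows)
  n_perm <- switch(blocks$mode,
    unrestricted = exp(log_multiset_perms(cls)),
    within_block = {
      lg <- vapply(blocks$members, function(ix) log_multiset_perms(cls[ix]), 0)
      exp(sum(lg))
    },
    whole_block = {
      bcls <- block_classes(blocks, cls)
      exp(log_multiset_perms(bcls))
    })
  n_flip <- if (blocks$mode == "whole_block") 2^blocks$B else 2^N
  out <- switch(regime, ee = n_perm, ise = n_flip, both = n_perm * n_flip)
  if (out < 2^53) round(out) else out
}

# class id per block from the ordered sequence of row classes it contains
block_classes <- function(blocks, cls) {
  key <- vapply(blocks$members, function(ix) paste(cls[ix], collapse = ","), "")
  as.integer(factor(key, levels = unique(key)))
}

# all distinct orderings of a multiset of class labels, as a matrix
# (rows = orderings); first row is the original sequence
multiset_orderings <- function(cls, limit = Inf) {
  n <- length(cls)
  # grow positions left to right, choosing which remaining class occupies each
  counts0 <- tabulate(cls)
  rec <- function(prefix, counts) {
    if (length(prefix) == n) return(list(prefix))
    out <- list()
    for (m in which(counts > 0L)) {
      counts[m] <- counts[m] - 1L
      out <- c(out, rec(c(prefix, m), counts))
      counts[m] <- counts[m] + 1L
      if (length(out) > limit) stop("enumeration exceeded limit")
    }
    out
  }
  seqs <- rec(integer(0), counts0)
  do.call(rbind, seqs)
}

# Map class-label assignment sequences to representative permutations.
# Two permutations are synonymous when, for every class of identical design
# rows, the same set of observations lands on that class's positions. Each
# equivalence class is identified by the assignment t (t_m = class receiving
# observation m); the representative fills the positions of each class (in
# order) with the observations assigned to it (in order). The original
# assignment (t = cls) maps to the identity.
sequence_to_perm <- function(seqs, cls) {
  pos_by_class <- split(seq_along(cls), cls)
  t(apply(seqs, 1L, function(t_assign) {
    out <- integer(length(t_assign))
    for (m in seq_along(pos_by_class))
      out[pos_by_class[[m]]] <- which(t_assign == m)
    out
  }))
}

# exhaustive unique permutations (as index vectors, identity included)
enumerate_perms <- function(blocks, cls) {
  switch(blocks$mode,
    unrestricted = sequence_to_perm(multiset_orderings(cls), cls),
    within_block = {
      per_block <- lapply(seq_along(blocks$members), function(b) {
        ix <- blocks$members[[b]]
        loc <- as.integer(factor(cls[ix])) # dense local class labels
        local_perms <- sequence_to_perm(multiset_orderings(loc), loc)
        matrix(ix[local_perms], nrow = nrow(local_perms))
      })
      # cartesian product across blocks
      combo <- as.matrix(expand.grid(lapply(per_block, function(m) seq_len(nrow(m)))))
      out <- matrix(0L, nrow(combo), blocks$N)
      for (b in seq_along(per_block))
        out[, blocks$members[[b]]] <- per_block[[b]][combo[, b], , drop = FALSE]
      out
    },
    whole_block = {
      bcls <- block_classes(blocks, cls)
      bperms <- sequence_to_perm(multiset_orderings(bcls), bcls)
      t(apply(bperms, 1L, function(bp) unlist(blocks$members[bp], use.names = FALSE)))
    })
}

# exhaustive sign-flip matrix (rows = flip patterns, radix-2 order,
# digit 1 -> +1, digit 0 -> -1); per block in whole_block mode
enumerate_flips <- function(blocks) {
  nf <- if (blocks$mode == "whole_block") blocks$B else blocks$N
  if (nf > 25L) stop("too many sign-flip units to enumerate exhaustively")
  ids <- 0:(2^nf - 1L)
  bits <- t(vapply(ids, function(i) as.integer(intToBits(i))[seq_len(nf)],
                   integer(nf)))
  flips <- 2L * bits - 1L
  if (blocks$mode == "whole_block") {
    out <- matrix(0L, nrow(flips), blocks$N)
    for (b in seq_len(blocks$B)) out[, blocks$members[[b]]] <- flips[, b]
    out
  } else flips
}

random_perm <- function(blocks) {
  switch(blocks$mode,
    unrestricted = sample.int(blocks$N),
    within_block = {
      out <- integer(blocks$N)
      for (ix in blocks$members) out[ix] <- ix[sample.int(length(ix))]
      out
    },
    whole_block = unlist(blocks$members[sample.int(blocks$B)], use.names = FALSE))
}

random_flip <- function(blocks) {
  if (blocks$mode == "whole_block") {
    per_block <- sample(c(-1L, 1L), blocks$B, replace = TRUE)
    out <- integer(blocks$N)
    for (b in seq_len(blocks$B)) out[blocks$members[[b]]] <- per_block[b]
    out
  } else sample(c(-1L, 1L), blocks$N, replace = TRUE)
}

#' Build a set of shufflings
#'
#' Constructs the ordered set of permutations and/or sign flips used to
#' build the permutation distribution, honouring the block structure. When
#' the number of unique shufflings (\code{\link{count_max_shufflings}}) does
#' not exceed \code{J_max}, the complete unique set is enumerated, the order
#' randomised, and the identity placed first; synonymous permutations
#' (identical after accounting for repeated rows of \code{X_rows}) are
#' generated once. Otherwise \code{J_max - 1} random shufflings are drawn by
#' conditional Monte Carlo (CMC) and prepended with the identity. Plain CMC
#' may draw duplicates; \code{dedup = TRUE} re-draws them.
#'
#' @param blocks Exchangeability blocks or \code{NULL}.
#' @param regime \code{"ee"}, \code{"ise"} or \code{"both"}.
#' @param J_max Maximum number of shufflings (including the identity).
#' @param seed Optional integer seed for order randomisation / CMC draws.
#' @param X_rows Matrix used to detect synonymous permutations (see
#'   \code{\link{count_max_shufflings}}).
#' @param N Number of observations if \code{blocks} and \code{X_rows} are NULL.
#' @param dedup Re-draw duplicated CMC shufflings.
#' @return Object of class \code{"shuffling_set"}: list with \code{perm}
#'   (J x N index matrix), \code{signs} (J x N matrix of +/-1), \code{J},
#'   \code{N}, \code{regime}, \code{method_of_generation}
#'   (\code{"exhaustive"} or \code{"cmc"}), and \code{n_possible}.
#' @export
enumerate_shufflings <- function(blocks = NULL, regime = c("ee", "ise", "both"),
                                 J_max = 1000L, seed = NULL, X_rows = NULL,
                                 N = NULL, dedup = FALSE) {
  regime <- match.arg(regime)
  if (J_max < 1L) stop("J_max must be at least 1")
  if (is.null(N)) N <- if (!is.null(X_rows)) nrow(as.matrix(X_rows)) else
    if (!is.null(blocks)) blocks$N else stop("cannot determine N")
  blocks <- as_blocks(blocks, N)
  if (!is.null(seed)) set.seed(seed)
  n_possible <- count_max_shufflings(blocks, X_rows, regime, N = N)
  cls <- if (is.null(X_rows)) seq_len(N) else row_classes(X_rows)

  if (n_possible <= J_max) {
    perms <- if (regime == "ise") matrix(seq_len(N), 1L) else enumerate_perms(blocks, cls)
    flips <- if (regime == "ee") matrix(1L, 1L, N) else enumerate_flips(blocks)
    grid <- expand.grid(p = seq_len(nrow(perms)), f = seq_len(nrow(flips)))
    perm <- perms[grid$p, , drop = FALSE]
    signs <- flips[grid$f, , drop = FALSE]
    J <- nrow(perm)
    id <- which(apply(perm == rep(seq_len(N), each = J), 1L, all) &
                apply(signs == 1L, 1L, all))[1L]
    rest <- setdiff(seq_len(J), id)
    if (length(rest) > 1L) rest <- sample(rest)
    ord <- c(id, rest)
    perm <- perm[ord, , drop = FALSE]
    signs <- signs[ord, , drop = FALSE]
    method <- "exhaustive"
  } else {
    J <- as.integer(J_max)
    perm <- matrix(rep(seq_len(N), J), J, N, byrow = TRUE)
    signs <- matrix(1L, J, N)
    draw <- function() {
      p <- if (regime != "ise") random_perm(blocks) else seq_len(N)
      s <- if (regime != "ee") random_flip(blocks) else rep(1L, N)
      list(p = p, s = s)
    }
    for (j in seq_len(J)[-1L]) {
      d <- draw()
      perm[j, ] <- d$p
      signs[j, ] <- d$s
    }
    if (dedup) {
      keys <- apply(cbind(perm, signs), 1L, paste, collapse = ",")
      tries <- 0L
      while (anyDuplicated(keys) && tries < 1000L) {
        dup <- which(duplicated(keys))
        for (j in dup) {
          d <- draw()
          perm[j, ] <- d$p
          signs[j, ] <- d$s
          keys[j] <- paste(c(perm[j, ], signs[j, ]), collapse = ",")
        }
        tries <- tries + 1L
      }
    }
    method <- "cmc"
  }
  structure(list(perm = perm, signs = signs, J = nrow(perm), N = N,
                 regime = regime, method_of_generation = method,
                 n_possible = n_possible, blocks = blocks),
            class = "shuffling_set")
}

#' Extract one shuffling from a set
#'
#' @param set A \code{shuffling_set}.
#' @param j Index (1 is always the identity).
#' @return List with \code{perm} and \code{signs} vectors.
#' @export
get_shuffling <- function(set, j) {
  list(perm = set$perm[j, ], signs = set$signs[j, ])
}

#' Apply a shuffling to the rows of a matrix
#'
#' Applies sign flips then row permutation: row \code{i} of the result is
#' \code{signs[perm[i]] * A[perm[i], ]}.
#'
#' @param sh A shuffling: list with integer \code{perm} (a permutation of
#'   \code{1:N}) and \code{signs} (+/-1 vector).
#' @param A Matrix (or vector) with N rows.
#' @return Shuffled matrix.
#' @export
apply_shuffling <- function(sh, A) {
  A <- as.matrix(A)
  if (nrow(A) != length(sh$perm)) stop("dimension mismatch")
  (sh$signs * A)[sh$perm, , drop = FALSE]
}

#' Invert a shuffling
#'
#' @param sh A shuffling (list with \code{perm}, \code{signs}).
#' @return The inverse shuffling: applying both in sequence is the identity.
#' @export
invert_shuffling <- function(sh) {
  inv <- order(sh$perm)
  list(perm = inv, signs = sh$signs[sh$perm])
}

#' @export
print.shuffling_set <- function(x, ...) {
  cat("Shuffling set:", x$J, "shufflings of", x$N, "observations (",
      x$method_of_generation, ", regime ", x$regime, ")\n", sep = "")
  cat("Unique shufflings possible:", format(x$n_possible, big.mark = ","), "\n")
  invisible(x)
}
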