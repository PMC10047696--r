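# Entanglement structure: the maximal separability partition P*(rho) of a
# labeled state, i.e. the finest grouping of qubits such that the state is a
# convex mixture of products across the groups (with the same grouping for
# every component of the mixture). Entangled groups are later treated as
# indivisible units when repertoires are factorized.
#
# Separability testing cascade, per candidate partition (finest first):
#   1. pure states: exact, via purity of every part's reduced state;
#   2. two-qubit states: the positive-partial-transpose (PPT) criterion is
#      exact for 2x2 cuts;
#   3. states diagonal in some product basis across the parts: explicitly
#      separable (each joint eigenvector is a product across parts);
#   4. otherwise PPT across all induced part-vs-rest cuts, which is only a
#      necessary condition beyond 2x2: a pass is tagged "ppt-heuristic".
# A PPT failure on any cut rejects the candidate definitively.

## ---- set partitions --------------------------------------------------------

#' All set partitions of a register
#'
#' Canonical order: number of parts descending (finest first); within equal
#' part counts, lexicographic by part structure in register order.
#'
#' @param units character vector.
#' @return list of partitions; each partition is a list of character vectors.
#' @export
set_partitions <- function(units) {
  units <- as.character(units)
  n <- length(units)
  if (n == 0) return(list(list()))
  recur <- function(items) {
    if (length(items) == 1) return(list(list(items)))
    first <- items[1]
    rest <- recur(items[-1])
    out <- list()
    for (p in rest) {
      # put first into each existing block, or in a new block
      for (k in seq_along(p)) {
        q <- p
        q[[k]] <- c(first, q[[k]])
        out[[length(out) + 1]] <- q
      }
      out[[length(out) + 1]] <- c(list(first), p)
    }
    out
  }
  parts <- recur(units)
  canon <- lapply(parts, function(p) {
    p <- lapply(p, function(b) b[order(match(b, units))])
    p[order(vapply(p, function(b) match(b[1], units), 1L))]
  })
  sig <- vapply(canon, function(p)
    paste(vapply(p, paste, "", collapse = ""), collapse = "|"), "")
  r <- vapply(canon, length, 1L)
  canon[order(-r, sig)]
}

## ---- purity / PPT ----------------------------------------------------------

#' Is a state pure?
#' @param rho a [qstate].
#' @param tol tolerance on `tr(rho^2) = 1`.
#' @return logical.
#' @export
is_pure <- function(rho, tol = 1e-8) {
  abs(purity(rho) - 1) < tol
}

# partial transpose over the units in `subset`
.partial_transpose <- function(rho, subset) {
  n <- length(rho$units)
  spos <- match(subset, rho$units)
  d <- 2^n
  m <- rho$matrix
  out <- base::matrix(0 + 0i, d, d)
  for (r in 0:(d - 1)) {
    rb <- .bits(r, n)
    for (cc in 0:(d - 1)) {
      cb <- .bits(cc, n)
      rb2 <- rb; cb2 <- cb
      rb2[spos] <- cb[spos]
      cb2[spos] <- rb[spos]
      out[.index_from_bits(rb2) + 1, .index_from_bits(cb2) + 1] <- m[r + 1, cc + 1]
    }
  }
  out
}

#' Peres-Horodecki (PPT) separability test across a bipartition
#'
#' For a two-qubit state split into single qubits the test is exact; for
#' larger cuts a negative partial transpose proves entanglement while a
#' positive one is only necessary for separability.
#'
#' @param rho a [qstate].
#' @param part1,part2 the two sides of the cut (must partition the register).
#' @param tol eigenvalue tolerance.
#' @return logical: `TRUE` if the partial transpose is positive
#'   semidefinite, with attribute `"exact"` indicating whether the test is
#'   conclusive for separability.
#' @export
is_separable_across <- function(rho, part1, part2, tol = .qphi_tol) {
  stopifnot(inherits(rho, "qstate"))
  if (!setequal(c(part1, part2), rho$units) || length(intersect(part1, part2)) > 0)
    stop("part1 and part2 must bipartition the register")
  pt <- .partial_transpose(rho, part2)
  ev <- eigen((pt + Conj(t(pt))) / 2, symmetric = TRUE, only.values = TRUE)$values
  ok <- min(Re(ev)) >= -sqrt(tol)
  attr(ok, "exact") <- (length(part1) == 1 && length(part2) == 1)
  attr(ok, "min_eigenvalue") <- min(Re(ev))
  ok
}

## ---- product-basis diagonalization ----------------------------------------

# candidate orthonormal bases for a part (columns are basis vectors)
.part_bases <- function(rho, part) {
  d <- 2^length(part)
  red <- partial_trace(rho, part)
  es <- eigen((red$matrix + Conj(t(red$matrix))) / 2, symmetric = TRUE)
  H1 <- matrix(c(1, 1, 1, -1), 2, 2) / sqrt(2)
  had <- Reduce(kronecker, rep(list(H1), length(part)))
  list(computational = diag(d) + 0i, hadamard = had + 0i, reduced = es$vectors)
}

# TRUE if rho is diagonal (within tol) in some product basis across `parts`
.product_basis_diagonal <- function(rho, parts, tol = 1e-8) {
  ord <- unlist(parts)
  rp <- permute_units(rho, ord)
  cand <- lapply(parts, .part_bases, rho = rho)
  idx <- expand.grid(lapply(cand, seq_along))
  for (r in seq_len(nrow(idx))) {
    B <- Reduce(kronecker, lapply(seq_along(parts),
                                  function(k) cand[[k]][[idx[r, k]]]))
    D <- Conj(t(B)) %*% rp$matrix %*% B
    if (max(Mod(D - diag(diag(D)))) < tol) return(TRUE)
  }
  FALSE
}

## ---- P* --------------------------------------------------------------------

.sep_partition <- function(parts, method, units) {
  parts <- lapply(parts, function(b) b[order(match(b, units))])
  parts <- parts[order(vapply(parts, function(b) match(b[1], units), 1L))]
  structure(list(parts = parts, r = length(parts), method = method),
            class = "sep_partition")
}

#' @export
print.sep_partition <- function(x, ...) {
  cat("<P*> r =", x$r, ":",
      paste(vapply(x$parts, paste, "", collapse = ""), collapse = " | "),
      sprintf("[%s]\n", x$method))
  invisible(x)
}

#' Separability structure of a pure state
#'
#' Finds the finest partition of the register such that the reduced state of
#' every part is itself pure (exact for pure states).
#'
#' @param rho a pure [qstate].
#' @param tol purity tolerance.
#' @return a `sep_partition` (fields `parts`, `r`, `method`).
#' @export
pure_state_partition <- function(rho, tol = 1e-8) {
  if (!is_pure(rho, tol)) stop("pure_state_partition: state is not pure")
  if (length(rho$units) == 1)
    return(.sep_partition(list(rho$units), "pure-reduction", rho$units))
  for (p in set_partitions(rho$units)) { # finest first
    if (length(p) == 1) next
    ok <- all(vapply(p, function(b) is_pure(partial_trace(rho, b), tol), TRUE))
    if (ok) return(.sep_partition(p, "pure-reduction", rho$units))
  }
  .sep_partition(list(rho$units), "pure-reduction", rho$units)
}

#' Maximal separability partition P* of a state
#'
#' Candidate partitions are scanned from finest to coarsest; the first one
#' passing the separability cascade (see the package vignette) is returned.
#' The coarsest partition (one part) is always valid, so the function always
#' returns. The `method` field records which test established the result;
#' `"ppt-heuristic"` marks the necessary-only regime beyond two qubits.
#'
#' @param rho a [qstate].
#' @param tol numerical tolerance.
#' @return a `sep_partition`.
#' @export
mixed_state_partition <- function(rho, tol = 1e-8) {
  units <- rho$units
  n <- length(units)
  if (n == 1) return(.sep_partition(list(units), "trivial", units))
  if (is_pure(rho, tol)) return(pure_state_partition(rho, tol))
  for (p in set_partitions(units)) {
    if (length(p) == 1) next
    # part-vs-rest PPT cuts: any failure is a definitive rejection
    ppt_ok <- TRUE
    for (b in p) {
      ok <- is_separable_across(rho, b, setdiff(units, b), tol)
      if (!ok) { ppt_ok <- FALSE; break }
    }
    if (!ppt_ok) next
    if (n == 2) return(.sep_partition(p, "two-qubit-exact", units))
    if (.product_basis_diagonal(rho, p, tol))
      return(.sep_partition(p, "product-basis", units))
    return(.sep_partition(p, "ppt-heuristic", units))
  }
  .sep_partition(list(units), "coarsest", units)
}
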