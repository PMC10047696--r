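# Density-matrix core: labeled qubit registers, composition, partial trace,
# eigendecomposition and state parsing.
#
# Conventions used throughout the package:
#  * a register is an ordered set of unit labels; the leftmost label is the
#    leftmost Kronecker factor (most significant bit of a basis index);
#  * basis-state strings read left to right in register order, with tokens
#    "0", "1", "+", "-" (Hadamard basis);
#  * all matrices are dense complex; registers of up to 3-4 qubits are the
#    intended problem size.

.qphi_tol <- 1e-9
.qphi_deg_tol <- 1e-8

## ---- bit bookkeeping -------------------------------------------------------

# bits of 0-based index i, length n, most significant first
.bits <- function(i, n) (i %/% 2^((n - 1):0)) %% 2

.index_from_bits <- function(b) sum(b * 2^((length(b) - 1):0))

# all nonempty subsets of a register, size ascending, lexicographic in
# register order within a size; this is the canonical purview order
unit_subsets <- function(units) {
  out <- list()
  for (k in seq_along(units)) {
    cmb <- utils::combn(units, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

## ---- qstate ----------------------------------------------------------------

#' Labeled density matrix
#'
#' Binds a square complex matrix to an ordered register of named qubit units.
#' The unit order defines the tensor-product order: the leftmost unit is the
#' leftmost Kronecker factor.
#'
#' @param matrix square complex (or numeric) matrix of dimension
#'   `2^length(units)`.
#' @param units character vector of unique unit labels, in register order.
#' @param tol numerical tolerance for the validity checks.
#' @param validate if `TRUE`, check Hermiticity, unit trace and positive
#'   semidefiniteness.
#' @return an object of class `qstate` with fields `units` and `matrix`.
#' @export
qstate <- function(matrix, units, tol = .qphi_tol, validate = TRUE) {
  units <- as.character(units)
  if (anyDuplicated(units)) stop("unit labels must be unique within a register")
  m <- base::matrix(as.complex(matrix), nrow = nrow(matrix))
  d <- 2^length(units)
  if (nrow(m) != d || ncol(m) != d)
    stop("matrix dimension ", nrow(m), " does not match register of ",
         length(units), " qubit(s)")
  if (validate) {
    if (max(Mod(m - Conj(t(m)))) > sqrt(tol))
      stop("matrix is not Hermitian within tolerance")
    if (abs(Re(sum(diag(m))) - 1) > sqrt(tol) || abs(Im(sum(diag(m)))) > sqrt(tol))
      stop("matrix does not have unit trace")
    ev <- eigen((m + Conj(t(m))) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -sqrt(tol))
      stop("matrix is not positive semidefinite (min eigenvalue ", min(ev), ")")
  }
  structure(list(units = units, matrix = m), class = "qstate")
}

#' @export
print.qstate <- function(x, digits = 4, ...) {
  cat("<qstate> register [", paste(x$units, collapse = " "), "], dim ",
      nrow(x$matrix), "x", ncol(x$matrix), "\n", sep = "")
  print(round(x$matrix, digits))
  invisible(x)
}

#' Purity tr(rho^2) of a labeled state
#' @param rho a [qstate].
#' @return real purity in (0, 1].
#' @export
purity <- function(rho) {
  stopifnot(inherits(rho, "qstate"))
  Re(sum(Mod(rho$matrix)^2))
}

## ---- composition and reordering -------------------------------------------

#' Compose labeled states by Kronecker product
#'
#' Units are concatenated in the order given; label sets must be disjoint.
#'
#' @param states list of [qstate] objects with pairwise disjoint unit labels.
#' @return a [qstate] over the concatenated register.
#' @export
compose <- function(states) {
  stopifnot(length(states) >= 1, all(vapply(states, inherits, TRUE, "qstate")))
  units <- unlist(lapply(states, `[[`, "units"))
  if (anyDuplicated(units))
    stop("label collision: units [",
         paste(unique(units[duplicated(units)]), collapse = ", "),
         "] appear in more than one factor")
  m <- Reduce(kronecker, lapply(states, `[[`, "matrix"))
  qstate(m, units, validate = FALSE)
}

#' Reorder the register of a labeled state
#'
#' Permutes the tensor factors so that the register reads `new_units`.
#'
#' @param rho a [qstate].
#' @param new_units permutation of `rho$units`.
#' @return a [qstate] on the permuted register.
#' @export
permute_units <- function(rho, new_units) {
  stopifnot(inherits(rho, "qstate"))
  new_units <- as.character(new_units)
  if (!setequal(new_units, rho$units) || length(new_units) != length(rho$units))
    stop("new_units must be a permutation of the register")
  if (identical(new_units, rho$units)) return(rho)
  n <- length(new_units)
  pos <- match(new_units, rho$units) # old position of each new factor
  d <- 2^n
  map <- vapply(0:(d - 1), function(b) {
    nb <- .bits(b, n)
    ob <- integer(n)
    ob[pos] <- nb
    .index_from_bits(ob)
  }, numeric(1))
  qstate(rho$matrix[map + 1, map + 1, drop = FALSE], new_units, validate = FALSE)
}

#' Partial trace onto a subset of units
#'
#' Reduces the state to the units in `keep`, preserving register order.
#'
#' @param rho a [qstate].
#' @param keep nonempty subset of `rho$units`.
#' @return a [qstate] over `keep` (in register order).
#' @export
partial_trace <- function(rho, keep) {
  stopifnot(inherits(rho, "qstate"))
  keep <- as.character(keep)
  if (!all(keep %in% rho$units)) stop("keep must be a subset of the register")
  if (length(keep) == 0) stop("keep must be nonempty")
  keep <- keep[order(match(keep, rho$units))]
  if (setequal(keep, rho$units)) return(rho)
  n <- length(rho$units)
  kpos <- match(keep, rho$units)
  tpos <- setdiff(seq_len(n), kpos)
  nk <- length(kpos); nt <- length(tpos)
  dk <- 2^nk; dt <- 2^nt
  weights <- 2^((n - 1):0)
  full_index <- function(a, e) {
    fb <- integer(n)
    fb[kpos] <- .bits(a, nk)
    fb[tpos] <- .bits(e, nt)
    sum(fb * weights)
  }
  out <- base::matrix(0 + 0i, dk, dk)
  for (e in 0:(dt - 1)) {
    idx <- vapply(0:(dk - 1), full_index, numeric(1), e = e) + 1
    out <- out + rho$matrix[idx, idx, drop = FALSE]
  }
  qstate(out, keep, validate = FALSE)
}

#' Maximally mixed state on a register
#' @param units nonempty character vector of unit labels.
#' @return the [qstate] I / 2^n over `units`.
#' @export
maximally_mixed <- function(units) {
  stopifnot(length(units) >= 1)
  d <- 2^length(units)
  qstate(diag(d) / d, units, validate = FALSE)
}

## ---- eigendecomposition ----------------------------------------------------

#' Eigendecomposition of a density matrix with degeneracy grouping
#'
#' Eigenvalues are returned in descending order; values within
#' `degeneracy_tol` of each other are grouped. Small negative eigenvalues
#' (within `-tol`) are clipped to zero and the spectrum renormalized so it
#' sums to the original trace.
#'
#' @param rho a [qstate] (or Hermitian complex matrix).
#' @param tol Hermiticity / clipping tolerance.
#' @param degeneracy_tol grouping tolerance for (near-)equal eigenvalues.
#' @return list with `values` (real, descending), `vectors` (orthonormal
#'   columns aligned to `values`) and `groups` (list of index vectors, one
#'   per degenerate group), class `eigensystem`.
#' @export
eigendecompose <- function(rho, tol = .qphi_tol, degeneracy_tol = .qphi_deg_tol) {
  m <- if (inherits(rho, "qstate")) rho$matrix else base::matrix(as.complex(rho), nrow = nrow(rho))
  if (max(Mod(m - Conj(t(m)))) > sqrt(tol))
    stop("eigendecompose: input is not Hermitian within tolerance")
  e <- eigen((m + Conj(t(m))) / 2, symmetric = TRUE)
  vals <- Re(e$values)
  if (min(vals) < -sqrt(tol))
    stop("eigendecompose: negative eigenvalue beyond tolerance (", min(vals), ")")
  tr <- sum(vals)
  vals[vals < tol & vals > -sqrt(tol)] <- pmax(vals[vals < tol & vals > -sqrt(tol)], 0)
  if (sum(vals) > 0) vals <- vals * tr / sum(vals)
  groups <- list()
  i <- 1
  while (i <= length(vals)) {
    j <- i
    while (j < length(vals) && abs(vals[j + 1] - vals[i]) <= degeneracy_tol) j <- j + 1
    groups[[length(groups) + 1]] <- i:j
    i <- j + 1
  }
  structure(list(values = vals, vectors = e$vectors, groups = groups),
            class = "eigensystem")
}

## ---- state parsing ---------------------------------------------------------

.token_kets <- list(
  "0" = c(1, 0), "1" = c(0, 1),
  "+" = c(1, 1) / sqrt(2), "-" = c(1, -1) / sqrt(2)
)

# pure-state vector from a token string like "10", "+0", "-+"
.ket_from_tokens <- function(spec) {
  spec <- chartr("−", "-", spec) # unicode minus
  toks <- strsplit(spec, "")[[1]]
  bad <- setdiff(toks, names(.token_kets))
  if (length(bad) > 0)
    stop("malformed state token(s): ", paste(bad, collapse = ", "))
  Reduce(kronecker, .token_kets[toks])
}

.named_kets <- function(name) {
  s2 <- sqrt(2)
  switch(tolower(name),
    "bell" = , "b+" = c(1, 0, 0, 1) / s2,
    "b-" = c(1, 0, 0, -1) / s2,
    "psi+" = c(0, 1, 1, 0) / s2,
    "psi-" = c(0, 1, -1, 0) / s2,
    "ghz" = c(1, 0, 0, 0, 0, 0, 0, 1) / s2,
    "w" = c(0, 1, 1, 0, 1, 0, 0, 0) / sqrt(3),
    NULL)
}

#' Parse a state specification into a labeled density matrix
#'
#' Accepts basis-token strings (`"10"`, `"+0"`, `"-+"`; characters `0`, `1`,
#' `+`, `-` read left to right in register order), named entangled states
#' (`"bell"`/`"B+"`, `"B-"`, `"psi+"`, `"psi-"`, `"ghz"`, `"w"`), an explicit
#' density matrix, an existing [qstate], or a convex mixture given as a named
#' numeric vector of weights, e.g. `c("00" = 0.5, "11" = 0.5)`.
#'
#' @param spec state specification (see Details).
#' @param units register the state lives on.
#' @return a [qstate].
#' @export
parse_state <- function(spec, units) {
  units <- as.character(units)
  d <- 2^length(units)
  if (inherits(spec, "qstate")) {
    if (!setequal(spec$units, units)) stop("state register does not match requested units")
    return(permute_units(spec, units))
  }
  if (is.matrix(spec)) return(qstate(spec, units))
  if (is.numeric(spec) && !is.null(names(spec))) { # mixture of token strings
    if (abs(sum(spec) - 1) > 1e-6) stop("mixture weights must sum to 1")
    if (any(spec < 0)) stop("mixture weights must be non-negative")
    m <- base::matrix(0 + 0i, d, d)
    for (k in seq_along(spec)) {
      comp <- parse_state(names(spec)[k], units)
      m <- m + spec[k] * comp$matrix
    }
    return(qstate(m, units, validate = FALSE))
  }
  if (is.character(spec) && length(spec) == 1) {
    v <- .named_kets(spec)
    if (is.null(v)) v <- .ket_from_tokens(spec)
    if (length(v) != d)
      stop("state '", spec, "' has dimension ", length(v),
           " but the register needs ", d)
    return(qstate(outer(as.complex(v), Conj(as.complex(v))), units, validate = FALSE))
  }
  stop("unsupported state specification")
}

## ---- labeling of states for reports ---------------------------------------

# Try to express a pure-state column vector as a product of basis tokens, or
# as one of the named entangled states; returns NA_character_ if unknown.
.label_vector <- function(v, nunits) {
  v <- as.complex(v)
  toks <- names(.token_kets)
  combos <- expand.grid(rep(list(toks), nunits), stringsAsFactors = FALSE)
  for (r in seq_len(nrow(combos))) {
    tv <- Reduce(kronecker, .token_kets[unlist(combos[r, ])])
    if (abs(Mod(sum(Conj(tv) * v))^2 - 1) < 1e-8)
      return(paste(rev(rev(unlist(combos[r, ]))), collapse = ""))
  }
  for (nm in c("B+", "B-", "psi+", "psi-", "GHZ", "W")) {
    tv <- .named_kets(nm)
    if (length(tv) == length(v) && abs(Mod(sum(Conj(tv) * v))^2 - 1) < 1e-8)
      return(nm)
  }
  NA_character_
}

#' Human-readable label for an intrinsic state
#'
#' Recognizes computational/Hadamard product states and the named entangled
#' states; degenerate eigenspaces are rendered as `span{...}`.
#'
#' @param vectors matrix whose columns span the intrinsic state (one column
#'   for a non-degenerate state).
#' @param nunits number of qubits the vectors live on.
#' @return a single string.
#' @export
state_label <- function(vectors, nunits) {
  vectors <- as.matrix(vectors)
  labs <- apply(vectors, 2, .label_vector, nunits = nunits)
  labs[is.na(labs)] <- "?"
  if (ncol(vectors) == 1) labs else paste0("span{", paste(labs, collapse = ","), "}")
}
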