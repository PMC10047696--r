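# Unitary dynamics: gate library, application and adjoint application, and
# embedding of reversible classical gates as permutation matrices.
#
# Only unitary channels are executable. General CPTP maps (Kraus sets) can be
# represented in the data model but are rejected by apply_channel(): the
# backward (cause) analysis is defined through the adjoint of a unitary and
# has no counterpart for non-unitary dynamics in this framework.

.gate_matrices <- function() {
  s2 <- sqrt(2)
  list(
    I = diag(2),
    X = matrix(c(0, 1, 1, 0), 2, 2),
    Z = diag(c(1, -1)),
    H = matrix(c(1, 1, 1, -1), 2, 2, byrow = TRUE) / s2,
    CNOT = matrix(c(1, 0, 0, 0,
                    0, 1, 0, 0,
                    0, 0, 0, 1,
                    0, 0, 1, 0), 4, 4, byrow = TRUE),
    SWAP = matrix(c(1, 0, 0, 0,
                    0, 0, 1, 0,
                    0, 1, 0, 0,
                    0, 0, 0, 1), 4, 4, byrow = TRUE),
    CZ = diag(c(1, 1, 1, -1))
  )
}

.gate_arity <- c(I = 1, X = 1, Z = 1, H = 1, CNOT = 2, SWAP = 2, CZ = 2)

#' Unitary channel on a labeled register
#'
#' @param matrix unitary complex matrix of dimension `2^length(units)`.
#' @param units register the channel acts on, in tensor order.
#' @param tol tolerance for the unitarity check.
#' @return object of class `qchannel`.
#' @export
qchannel <- function(matrix, units, tol = .qphi_tol) {
  units <- as.character(units)
  m <- base::matrix(as.complex(matrix), nrow = nrow(matrix))
  d <- 2^length(units)
  if (nrow(m) != d || ncol(m) != d)
    stop("channel dimension does not match register size")
  if (max(Mod(Conj(t(m)) %*% m - diag(d))) > sqrt(tol))
    stop("matrix is not unitary within tolerance; ",
         "non-unitary dynamics (measurements, general Kraus maps) are unsupported")
  structure(list(units = units, matrix = m), class = "qchannel")
}

#' @export
print.qchannel <- function(x, digits = 4, ...) {
  cat("<qchannel> register [", paste(x$units, collapse = " "), "]\n", sep = "")
  print(round(x$matrix, digits))
  invisible(x)
}

#' Standard gates by name
#'
#' Available single-qubit gates: `I`, `X`, `Z`, `H`; two-qubit gates: `CNOT`
#' (control = first unit of the pair), `SWAP`, `CZ`. Compound names joined by
#' `⊗`, `x` or `*` (e.g. `"I⊗CNOT"`, `"H x I"`) are built as Kronecker
#' products consuming units left to right.
#'
#' @param name gate name, possibly compound.
#' @param units register, with total size matching the gate arity.
#' @return a [qchannel].
#' @export
named_gate <- function(name, units) {
  units <- as.character(units)
  toks <- toupper(trimws(strsplit(name, "[⊗x*]")[[1]]))
  toks <- toks[nzchar(toks)]
  gm <- .gate_matrices()
  if (!all(toks %in% names(gm)))
    stop("unknown gate(s): ", paste(setdiff(toks, names(gm)), collapse = ", "))
  if (sum(.gate_arity[toks]) != length(units))
    stop("gate '", name, "' acts on ", sum(.gate_arity[toks]),
         " qubit(s) but the register has ", length(units))
  U <- Reduce(kronecker, gm[toks])
  qchannel(U, units)
}

#' Permutation unitary from the truth table of a reversible classical gate
#'
#' @param table named character vector mapping every input bit-string to an
#'   output bit-string; must be a bijection on `{0,1}^n`.
#' @param units register of size `n`.
#' @return a [qchannel] whose matrix is the permutation `P[out, in] = 1`.
#' @export
from_truth_table <- function(table, units) {
  units <- as.character(units)
  n <- length(units)
  d <- 2^n
  ins <- names(table)
  outs <- as.character(table)
  all_states <- vapply(0:(d - 1), function(i) paste(.bits(i, n), collapse = ""), "")
  if (!setequal(ins, all_states))
    stop("truth table must cover every input bit-string exactly once")
  if (anyDuplicated(outs) || !setequal(outs, all_states))
    stop("truth table is not reversible (outputs are not a bijection)")
  P <- base::matrix(0, d, d)
  for (k in seq_along(ins)) {
    i <- .index_from_bits(as.integer(strsplit(ins[k], "")[[1]]))
    o <- .index_from_bits(as.integer(strsplit(outs[k], "")[[1]]))
    P[o + 1, i + 1] <- 1
  }
  qchannel(P, units)
}

#' Apply a unitary channel forward: U rho U^dagger
#'
#' @param U a [qchannel].
#' @param rho a [qstate] over the same register (any unit order).
#' @return the evolved [qstate], on the channel's register order.
#' @export
apply_channel <- function(U, rho) {
  stopifnot(inherits(U, "qchannel"), inherits(rho, "qstate"))
  if (!setequal(U$units, rho$units))
    stop("state register does not match channel register")
  rho <- permute_units(rho, U$units)
  qstate(U$matrix %*% rho$matrix %*% Conj(t(U$matrix)), U$units, validate = FALSE)
}

#' Apply the adjoint of a unitary channel: U^dagger rho U
#'
#' The adjoint propagates a state backwards through a reversible update and
#' is the backbone of the cause-repertoire computation.
#'
#' @inheritParams apply_channel
#' @return the back-propagated [qstate].
#' @export
apply_adjoint <- function(U, rho) {
  stopifnot(inherits(U, "qchannel"), inherits(rho, "qstate"))
  if (!setequal(U$units, rho$units))
    stop("state register does not match channel register")
  rho <- permute_units(rho, U$units)
  qstate(Conj(t(U$matrix)) %*% rho$matrix %*% U$matrix, U$units, validate = FALSE)
}

#' Identity channel on a register
#' @param units register.
#' @return a [qchannel].
#' @export
identity_channel <- function(units) {
  qchannel(diag(2^length(units)), units)
}

#' Is a channel (numerically) a permutation of computational basis states?
#' @param U a [qchannel].
#' @param tol tolerance.
#' @return logical.
#' @export
is_permutation_channel <- function(U, tol = 1e-9) {
  m <- Mod(U$matrix)
  all(abs(m - round(m)) < tol) && all(abs(Im(U$matrix)) < tol) &&
    all(abs(Re(U$matrix) - round(Re(U$matrix))) < tol) && all(round(m) %in% c(0, 1))
}
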