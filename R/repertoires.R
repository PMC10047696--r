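# Quantum cause and effect repertoires with causal marginalization.
#
# The effect repertoire of a mechanism m over a purview Z is the state of Z
# after the update, with everything outside the mechanism replaced by
# independent maximally mixed noise, factorized across the entanglement
# structure P* of the conditional purview state so that extraneous
# correlations induced from outside the mechanism are discounted while
# genuine entanglement within the purview is preserved.
#
# The cause repertoire propagates each conditionally independent mechanism
# part backwards through the adjoint channel (complement noised), combines
# the per-part constraints by matrix product over the purview space and
# trace-normalizes.

#' Mechanism: a subset of the register in its current (reduced) state
#'
#' @param state a [qstate]; either the full system state (then reduced onto
#'   `units`) or a state already on `units`.
#' @param units nonempty subset of the state's register.
#' @return object of class `mechanism` with fields `units` and `state`.
#' @export
mechanism <- function(state, units = state$units) {
  stopifnot(inherits(state, "qstate"), length(units) >= 1)
  units <- as.character(units)
  units <- units[order(match(units, state$units))]
  st <- if (setequal(units, state$units)) permute_units(state, units)
        else partial_trace(state, units)
  structure(list(units = units, state = st), class = "mechanism")
}

#' @export
print.mechanism <- function(x, ...) {
  cat("<mechanism> on [", paste(x$units, collapse = " "), "]\n", sep = "")
  print(x$state)
  invisible(x)
}

.repertoire <- function(state, purview, direction, factorization,
                        mechanism_units, empty = FALSE) {
  structure(list(state = state, purview = purview, direction = direction,
                 factorization = factorization,
                 mechanism_units = mechanism_units, empty = empty),
            class = "repertoire")
}

#' @export
print.repertoire <- function(x, ...) {
  cat("<repertoire> ", x$direction, " of [",
      paste(x$mechanism_units, collapse = " "), "] over [",
      paste(x$purview, collapse = " "), "]",
      if (x$empty) " (EMPTY: zero-trace cause product)", "\n", sep = "")
  if (!x$empty) print(x$state)
  invisible(x)
}

#' Raw conditional purview state (before entanglement factorization)
#'
#' Composes the mechanism state with maximally mixed noise on its
#' complement, applies the channel (effect) or its adjoint (cause), and
#' reduces onto the purview.
#'
#' @param U a [qchannel] over the full register.
#' @param m a [mechanism].
#' @param Z nonempty purview, subset of the register.
#' @param direction `"effect"` or `"cause"`.
#' @return a [qstate] over `Z`.
#' @export
raw_conditional <- function(U, m, Z, direction = c("effect", "cause")) {
  direction <- match.arg(direction)
  stopifnot(inherits(U, "qchannel"), inherits(m, "mechanism"))
  Z <- as.character(Z)
  if (!all(Z %in% U$units) || length(Z) == 0)
    stop("purview must be a nonempty subset of the channel register")
  rest <- setdiff(U$units, m$units)
  joint <- if (length(rest) > 0) compose(list(m$state, maximally_mixed(rest)))
           else m$state
  joint <- permute_units(joint, U$units)
  out <- if (direction == "effect") apply_channel(U, joint)
         else apply_adjoint(U, joint)
  partial_trace(out, Z)
}

#' Quantum effect repertoire
#'
#' The raw conditional state over the purview is computed first; its
#' entanglement structure P* is identified; then each P*-part receives an
#' independently recomputed conditional state (independent noising per
#' part), and the parts are Kronecker-composed in register order.
#'
#' @inheritParams raw_conditional
#' @return a `repertoire` object.
#' @export
effect_repertoire <- function(U, m, Z) {
  Z <- as.character(Z)
  Z <- Z[order(match(Z, U$units))]
  raw <- raw_conditional(U, m, Z, "effect")
  pstar <- mixed_state_partition(raw)
  if (pstar$r == 1) {
    return(.repertoire(raw, Z, "effect", pstar$parts, m$units))
  }
  parts <- lapply(pstar$parts, function(zi) raw_conditional(U, m, zi, "effect"))
  st <- permute_units(compose(parts), Z)
  .repertoire(st, Z, "effect", pstar$parts, m$units)
}

#' Quantum cause repertoire
#'
#' The mechanism state is factorized by its own entanglement structure P*;
#' each part is propagated backwards through the adjoint channel with its
#' complement maximally mixed; the per-part constraints over the purview are
#' combined by matrix product and trace-normalized. A non-Hermitian product
#' (possible for non-commuting parts) is symmetrized as `(X + X^dagger)/2`
#' with a warning; a zero-trace product yields an empty repertoire.
#'
#' @inheritParams raw_conditional
#' @param tol numerical tolerance.
#' @return a `repertoire` object (check the `empty` field).
#' @export
cause_repertoire <- function(U, m, Z, tol = .qphi_tol) {
  Z <- as.character(Z)
  Z <- Z[order(match(Z, U$units))]
  pstar <- mixed_state_partition(m$state)
  mats <- lapply(pstar$parts, function(mi) {
    mi_mech <- mechanism(m$state, mi)
    raw_conditional(U, mi_mech, Z, "cause")$matrix
  })
  X <- Reduce(`%*%`, mats)
  resid <- max(Mod(X - Conj(t(X))))
  if (resid > sqrt(tol))
    warning("non-commuting cause-repertoire parts; symmetrizing ",
            "(anti-Hermitian residual ", format(resid), ")")
  X <- (X + Conj(t(X))) / 2
  tr <- Re(sum(diag(X)))
  if (tr < tol) {
    return(.repertoire(NULL, Z, "cause", pstar$parts, m$units, empty = TRUE))
  }
  .repertoire(qstate(X / tr, Z, validate = FALSE), Z, "cause",
              pstar$parts, m$units)
}

#' Repertoire of a mechanism over a purview (dispatch on direction)
#' @inheritParams raw_conditional
#' @return a `repertoire` object.
#' @export
repertoire <- function(U, m, Z, direction = c("effect", "cause")) {
  direction <- match.arg(direction)
  if (direction == "effect") effect_repertoire(U, m, Z) else cause_repertoire(U, m, Z)
}

#' Unconstrained repertoire
#'
#' With unitary dynamics the unconstrained cause and effect repertoires both
#' equal the maximally mixed state on the purview.
#'
#' @param Z nonempty purview.
#' @param direction `"effect"` or `"cause"` (recorded, does not change the
#'   result).
#' @return a `repertoire` object.
#' @export
unconstrained_repertoire <- function(Z, direction = c("effect", "cause")) {
  direction <- match.arg(direction)
  Z <- as.character(Z)
  .repertoire(maximally_mixed(Z), Z, direction,
              as.list(Z), character(0))
}
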