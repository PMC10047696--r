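# Classical reference engine: mechanism integrated information for discrete
# causal networks given by a transition probability matrix (TPM).
#
# This module is the independent oracle for the quantum pipeline: for a
# reversible logic gate applied to a computational basis state, the quantum
# analysis must reproduce these results exactly. The combinatorics
# (disintegrating partitions, normalization, tie rules) are shared with the
# quantum modules so that convergence tests exercise the genuinely
# different parts — the repertoires and the difference measure.
#
# State indexing: rows are input states, columns output states; a state
# index encodes unit values big-endian in register order (leftmost unit =
# most significant bit), matching the quantum basis convention.

#' Classical system: TPM plus unit labels
#'
#' @param tpm row-stochastic matrix of dimension `2^n x 2^n`: rows index
#'   input states, columns output states (big-endian in register order).
#' @param units character vector of `n` unit labels.
#' @return object of class `classical_system`.
#' @export
classical_system <- function(tpm, units) {
  units <- as.character(units)
  d <- 2^length(units)
  tpm <- as.matrix(tpm)
  if (nrow(tpm) != d || ncol(tpm) != d)
    stop("TPM dimension does not match register size")
  if (any(tpm < -1e-12) || max(abs(rowSums(tpm) - 1)) > 1e-9)
    stop("TPM rows must be non-negative and sum to 1")
  structure(list(tpm = tpm, units = units), class = "classical_system")
}

#' Deterministic TPM from a reversible truth table
#' @inheritParams from_truth_table
#' @return a `classical_system`.
#' @export
classical_from_truth_table <- function(table, units) {
  U <- from_truth_table(table, units)
  classical_system(t(Re(U$matrix)), units) # TPM rows = inputs
}

# state strings <-> indices
.state_string <- function(i, n) paste(.bits(i, n), collapse = "")

#' Write / read a TPM as CSV (states as row/column names)
#' @param sys a `classical_system`.
#' @param path file path.
#' @export
write_tpm <- function(sys, path) {
  n <- length(sys$units)
  m <- sys$tpm
  labs <- vapply(0:(2^n - 1), .state_string, "", n = n)
  dimnames(m) <- list(labs, labs)
  utils::write.csv(as.data.frame(m), path)
  invisible(path)
}

#' @rdname write_tpm
#' @param units unit labels for the system being read.
#' @export
read_tpm <- function(path, units) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  classical_system(m, units)
}

## ---- repertoires -----------------------------------------------------------

# rows of the TPM consistent with a named mechanism assignment m
.consistent_rows <- function(sys, m) {
  n <- length(sys$units)
  pos <- match(names(m), sys$units)
  idx <- 0:(2^n - 1)
  keep <- rep(TRUE, length(idx))
  for (k in seq_along(pos)) {
    bit <- (idx %/% 2^(n - pos[k])) %% 2
    keep <- keep & (bit == m[k])
  }
  which(keep)
}

# single-unit effect repertoire p(z_i,t+1 | m, rest uniform); empty m gives
# the fully noised repertoire (uniform interventional distribution over all
# inputs)
.pe_unit <- function(sys, m, zu) {
  n <- length(sys$units)
  rows <- if (length(m) == 0) seq_len(2^n) else .consistent_rows(sys, m)
  joint <- colMeans(sys$tpm[rows, , drop = FALSE])
  zpos <- match(zu, sys$units)
  out <- numeric(2)
  idx <- 0:(2^n - 1)
  bit <- (idx %/% 2^(n - zpos)) %% 2
  out[1] <- sum(joint[bit == 0])
  out[2] <- sum(joint[bit == 1])
  out
}

.classical_repertoire <- function(probs, units) {
  structure(list(units = units, probs = probs), class = "classical_repertoire")
}

#' Classical effect repertoire over a purview
#'
#' Product, over purview units, of single-unit conditional distributions
#' with everything outside the mechanism causally marginalized (independent
#' uniform interventional noise per purview unit).
#'
#' @param sys a `classical_system`.
#' @param m named integer vector: mechanism unit values (names are unit
#'   labels); may be empty for the fully noised repertoire.
#' @param Z purview units.
#' @return a `classical_repertoire` (fields `units`, `probs`; big-endian
#'   state order).
#' @export
classical_effect_repertoire <- function(sys, m, Z) {
  Z <- as.character(Z)
  Z <- Z[order(match(Z, sys$units))]
  per_unit <- lapply(Z, .pe_unit, sys = sys, m = m)
  .classical_repertoire(as.vector(Reduce(kronecker, per_unit)), Z)
}

#' Classical cause repertoire over a purview
#'
#' Bayesian inversion, with a uniform prior over purview states, of the
#' product of per-mechanism-unit likelihoods (each likelihood is a
#' single-unit effect repertoire of the purview state).
#'
#' @inheritParams classical_effect_repertoire
#' @return a `classical_repertoire`; all-zero likelihood gives a flagged
#'   zero vector.
#' @export
classical_cause_repertoire <- function(sys, m, Z) {
  Z <- as.character(Z)
  Z <- Z[order(match(Z, sys$units))]
  nz <- length(Z)
  probs <- numeric(2^nz)
  for (z in 0:(2^nz - 1)) {
    zassign <- stats::setNames(.bits(z, nz), Z)
    lik <- 1
    for (k in seq_along(m)) {
      pu <- .pe_unit(sys, zassign, names(m)[k])
      lik <- lik * pu[m[k] + 1]
    }
    probs[z + 1] <- lik
  }
  s <- sum(probs)
  if (s > 0) probs <- probs / s
  rep <- .classical_repertoire(probs, Z)
  rep$empty <- (s == 0)
  rep
}

#' Unconstrained classical repertoire
#'
#' Effect side: the marginal of the effect repertoire over a uniform
#' mechanism distribution; cause side: uniform over purview states.
#'
#' @inheritParams classical_effect_repertoire
#' @param M mechanism units (values marginalized over).
#' @param direction `"effect"` or `"cause"`.
#' @export
classical_unconstrained <- function(sys, M, Z, direction = c("effect", "cause")) {
  direction <- match.arg(direction)
  Z <- as.character(Z)
  Z <- Z[order(match(Z, sys$units))]
  if (direction == "cause" || length(M) == 0)
    return(.classical_repertoire(rep(1 / 2^length(Z), 2^length(Z)), Z))
  nm <- length(M)
  acc <- 0
  for (mv in 0:(2^nm - 1)) {
    m <- stats::setNames(.bits(mv, nm), M)
    acc <- acc + classical_effect_repertoire(sys, m, Z)$probs
  }
  .classical_repertoire(acc / 2^nm, Z)
}

## ---- difference measures ---------------------------------------------------

#' Classical intrinsic difference ID(P, Q) = max_a p_a log2(p_a / q_a)
#'
#' @param P,Q probability vectors of equal length; `Q` must be positive
#'   wherever `P` is (else `Inf`).
#' @return list: `value` (ibits), `states` (0-based optimizing state
#'   indices, ties grouped), `terms`.
#' @export
classical_id <- function(P, Q) {
  stopifnot(length(P) == length(Q))
  terms <- numeric(length(P))
  for (a in seq_along(P)) {
    terms[a] <- if (P[a] <= 1e-12) 0
                else if (Q[a] <= 1e-12) Inf
                else P[a] * (log2(P[a]) - log2(Q[a]))
  }
  v <- max(terms)
  list(value = v, states = which(terms >= v - 1e-9) - 1L, terms = terms)
}

#' Kullback-Leibler divergence in bits
#' @inheritParams classical_id
#' @return non-negative real (bits).
#' @export
classical_kld <- function(P, Q) {
  s <- 0
  for (a in seq_along(P)) {
    if (P[a] <= 1e-12) next
    if (Q[a] <= 1e-12) return(Inf)
    s <- s + P[a] * (log2(P[a]) - log2(Q[a]))
  }
  s
}

## ---- phi -------------------------------------------------------------------

# reorder a probability vector over `from` units to `to` unit order
.perm_probs <- function(probs, from, to) {
  n <- length(from)
  if (identical(from, to)) return(probs)
  pos <- match(to, from)
  d <- 2^n
  out <- numeric(d)
  for (b in 0:(d - 1)) {
    nb <- .bits(b, n)
    ob <- integer(n)
    ob[pos] <- nb
    out[b + 1] <- probs[.index_from_bits(ob) + 1]
  }
  out
}

.classical_partitioned <- function(sys, m, Z, theta, direction) {
  pieces <- list()
  ord <- character(0)
  for (p in theta$parts) {
    if (length(p$z) == 0) next
    zu <- p$z[order(match(p$z, sys$units))]
    rp <- if (direction == "effect") {
      classical_effect_repertoire(sys, m[names(m) %in% p$m], zu)
    } else if (length(p$m) == 0) {
      .classical_repertoire(rep(1 / 2^length(zu), 2^length(zu)), zu)
    } else {
      classical_cause_repertoire(sys, m[names(m) %in% p$m], zu)
    }
    pieces[[length(pieces) + 1]] <- rp$probs
    ord <- c(ord, zu)
  }
  Zr <- Z[order(match(Z, sys$units))]
  .perm_probs(as.vector(Reduce(kronecker, pieces)), ord, Zr)
}

#' Classical mechanism integrated information
#'
#' Mirrors the quantum pipeline: intrinsic states selected against the
#' unconstrained repertoire, phi evaluated over those states against the
#' partitioned repertoire, MIP search with shared partition enumeration and
#' normalization, purview maximization with the larger-purview tie rule.
#'
#' @param sys a `classical_system`.
#' @param m named integer vector: mechanism unit values.
#' @param direction `"effect"` or `"cause"`.
#' @param measure `"id"` (intrinsic difference, the standard measure) or
#'   `"kld"` (relative entropy, for comparison; not state-specific).
#' @return list (class `classical_distinction`): `phi`, `purview`,
#'   `states` (0-based optimizing purview states at the maximal purview),
#'   `state_labels`, `mip`, `ties`, `all_purviews`.
#' @export
classical_phi <- function(sys, m, direction = c("effect", "cause"),
                          measure = c("id", "kld")) {
  direction <- match.arg(direction)
  measure <- match.arg(measure)
  M <- names(m)
  purviews <- unit_subsets(sys$units)
  res <- lapply(purviews, function(Z) {
    rep <- if (direction == "effect") classical_effect_repertoire(sys, m, Z)
           else classical_cause_repertoire(sys, m, Z)
    if (isTRUE(rep$empty))
      return(list(phi = 0, states = integer(0), mip = NULL))
    unc <- classical_unconstrained(sys, M, Z, direction)
    sel <- classical_id(rep$probs, unc$probs)
    ze <- sel$states + 1L
    thetas <- enumerate_partitions(M, Z)
    phis <- vapply(thetas, function(th) {
      pq <- .classical_partitioned(sys, m, Z, th, direction)
      if (measure == "kld") return(classical_kld(rep$probs, pq))
      best <- -Inf
      for (a in ze) {
        pa <- rep$probs[a]
        val <- if (pa <= 1e-12) 0
               else if (pq[a] <= 1e-12) Inf
               else pa * (log2(pa) - log2(pq[a]))
        if (val > best) best <- val
      }
      max(best, 0)
    }, 0)
    norms <- vapply(thetas, normalization_factor, 1)
    i <- which.min(phis / norms)
    list(phi = phis[i], states = sel$states, mip = thetas[[i]],
         repertoire = rep)
  })
  phis <- vapply(res, `[[`, 0, "phi")
  sizes <- vapply(purviews, length, 1L)
  top <- which(phis >= max(phis) - 1e-9)
  best_i <- top[order(-sizes[top], top)][1]
  ties <- setdiff(top[sizes[top] == sizes[best_i]], best_i)
  nz <- length(purviews[[best_i]])
  structure(list(
    mechanism = m,
    direction = direction,
    phi = phis[best_i],
    purview = purviews[[best_i]],
    states = res[[best_i]]$states,
    state_labels = vapply(res[[best_i]]$states, .state_string, "", n = nz),
    repertoire = res[[best_i]]$repertoire,
    mip = res[[best_i]]$mip,
    ties = lapply(ties, function(i)
      list(purview = purviews[[i]], states = res[[i]]$states)),
    all_purviews = Map(function(Z, ph) list(purview = Z, phi = ph),
                       purviews, phis)
  ), class = "classical_distinction")
}

#' @export
print.classical_distinction <- function(x, digits = 4, ...) {
  cat(sprintf("<classical distinction> %s of [%s=%s]: phi = %s over [%s] = {%s}\n",
              x$direction, paste(names(x$mechanism), collapse = ""),
              paste(x$mechanism, collapse = ""),
              format(round(x$phi, digits)),
              paste(x$purview, collapse = ""),
              paste(x$state_labels, collapse = ",")))
  invisible(x)
}
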