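# Disintegrating partitions and the minimum-information-partition search.
#
# A disintegrating partition theta of (mechanism M, purview Z) is a set of
# k >= 2 pairs (M_i, Z_i) such that the nonempty M_i partition M, the
# nonempty Z_i partition Z, no pair is (empty, empty), and a pair carrying
# the whole mechanism must carry an empty purview. Every theta therefore
# either cuts the mechanism into independent parts or severs all
# mechanism-purview connections.
#
# phi(m, Z, theta) compares the repertoire to its theta-partitioned version
# at the intrinsic state selected against the unconstrained repertoire. The
# minimum information partition minimizes phi normalized by the number of
# mechanism-unit x purview-unit connections the partition severs; the
# reported phi at the MIP is unnormalized.

## ---- enumeration -----------------------------------------------------------

.perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in .perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

.theta <- function(parts, M, Z) {
  structure(list(parts = parts, M = M, Z = Z), class = "theta_partition")
}

#' @export
format.theta_partition <- function(x, ...) {
  paste(vapply(x$parts, function(p) {
    paste0(if (length(p$m)) paste(p$m, collapse = "") else "0",
           ":",
           if (length(p$z)) paste(p$z, collapse = "") else "0")
  }, ""), collapse = " | ")
}

#' @export
print.theta_partition <- function(x, ...) {
  cat("<theta>", format(x), "\n")
  invisible(x)
}

#' Enumerate all disintegrating partitions of (M, Z)
#'
#' Complete and duplicate-free; parts are unordered but returned in a
#' deterministic canonical order. Always includes the total cut
#' `{(M, 0), (0, Z)}`; for a single-unit mechanism the only partitions are
#' total cuts, possibly splitting the purview.
#'
#' @param M,Z nonempty character vectors of mechanism and purview units.
#' @return list of `theta_partition` objects.
#' @export
enumerate_partitions <- function(M, Z) {
  M <- as.character(M); Z <- as.character(Z)
  if (length(M) == 0 || length(Z) == 0)
    stop("mechanism and purview must both be nonempty")
  PMs <- set_partitions(M)
  PZs <- set_partitions(Z)
  out <- list()
  for (pm in PMs) for (pz in PZs) {
    p <- length(pm); q <- length(pz)
    for (k in 0:min(p, q)) {
      msubs <- if (k == 0) list(integer(0)) else utils::combn(p, k, simplify = FALSE)
      zsubs <- if (k == 0) list(integer(0)) else utils::combn(q, k, simplify = FALSE)
      for (mi in msubs) {
        if (p == 1 && k == 1) next        # whole mechanism must pair with empty purview
        for (zi in zsubs) for (zp in .perms(zi)) {
          nparts <- p + q - k
          if (nparts < 2) next
          parts <- list()
          for (t in seq_len(k))
            parts[[length(parts) + 1]] <- list(m = pm[[mi[t]]], z = pz[[zp[t]]])
          for (t in setdiff(seq_len(p), mi))
            parts[[length(parts) + 1]] <- list(m = pm[[t]], z = character(0))
          for (t in setdiff(seq_len(q), zi))
            parts[[length(parts) + 1]] <- list(m = character(0), z = pz[[t]])
          out[[length(out) + 1]] <- .theta(parts, M, Z)
        }
      }
    }
  }
  out
}

#' Normalization factor of a disintegrating partition
#'
#' The number of mechanism-unit x purview-unit pairs whose connection
#' crosses parts: `|M||Z| - sum_i |M_i||Z_i|`.
#'
#' @param theta a `theta_partition`.
#' @return positive integer.
#' @export
normalization_factor <- function(theta) {
  stopifnot(inherits(theta, "theta_partition"))
  kept <- sum(vapply(theta$parts, function(p) length(p$m) * length(p$z), 1))
  length(theta$M) * length(theta$Z) - kept
}

## ---- partitioned repertoires ----------------------------------------------

# per-part repertoire with memoization; cache maps
# "direction;m-units;z-units" -> qstate (or NULL for an empty cause product)
.part_repertoire <- function(U, m, mu, zu, direction, cache) {
  key <- paste(direction, paste(mu, collapse = ","), paste(zu, collapse = ","),
               sep = ";")
  hit <- get0(key, envir = cache, ifnotfound = NULL)
  if (!is.null(hit)) return(hit)
  st <- if (length(mu) == 0) {
    maximally_mixed(zu)
  } else {
    subm <- mechanism(m$state, mu)
    r <- repertoire(U, subm, zu, direction)
    if (r$empty) NULL else r$state
  }
  res <- if (is.null(st)) list(empty = TRUE) else st
  assign(key, res, envir = cache)
  res
}

#' Partitioned repertoire under a disintegrating partition
#'
#' Each part's repertoire is computed from that part's mechanism units only
#' (everything else noised) and is itself entanglement-factorized; an empty
#' mechanism part contributes the maximally mixed state on its purview
#' part; an empty purview part contributes the scalar 1. Parts are
#' Kronecker-composed and reordered to register order.
#'
#' @param U a [qchannel].
#' @param m the full [mechanism].
#' @param Z the purview.
#' @param theta a `theta_partition` over (`m$units`, `Z`).
#' @param direction `"effect"` or `"cause"`.
#' @param cache optional environment for per-part memoization.
#' @return a [qstate] over `Z`, or `NULL` if a cause part had an empty
#'   (zero-trace) repertoire.
#' @export
partitioned_repertoire <- function(U, m, Z, theta,
                                   direction = c("effect", "cause"),
                                   cache = new.env(parent = emptyenv())) {
  direction <- match.arg(direction)
  Z <- as.character(Z)
  Z <- Z[order(match(Z, U$units))]
  pieces <- list()
  for (p in theta$parts) {
    if (length(p$z) == 0) next
    st <- .part_repertoire(U, m, p$m, p$z, direction, cache)
    if (is.list(st) && isTRUE(st$empty)) return(NULL)
    pieces[[length(pieces) + 1]] <- st
  }
  permute_units(compose(pieces), Z)
}

## ---- phi -------------------------------------------------------------------

# intrinsic-state selection against the unconstrained repertoire: with a
# maximally mixed sigma the optimizer is the leading (possibly degenerate)
# eigengroup of the repertoire
.intrinsic_group <- function(esys) {
  idx <- esys$groups[[1]]
  list(p = esys$values[idx[1]], vectors = esys$vectors[, idx, drop = FALSE],
       indices = idx)
}

# phi(m, Z, theta) at the fixed intrinsic eigenstate(s); degenerate
# eigenspace: max over an orthonormal basis of the eigenspace
.phi_at_state <- function(group, prep_esys, tol = .qphi_tol) {
  p <- group$p
  if (p <= tol) return(0)
  q <- prep_esys$values
  best <- -Inf
  for (k in seq_len(ncol(group$vectors))) {
    v <- group$vectors[, k]
    P <- Mod(Conj(t(prep_esys$vectors)) %*% v)^2
    js <- which(P > tol)
    val <- if (any(q[js] <= tol)) Inf
           else p * (log2(p) - sum(P[js] * log2(q[js])))
    if (val > best) best <- val
  }
  max(best, 0)
}

#' Integrated information for a fixed disintegrating partition
#'
#' Evaluates phi(m, Z, theta) at the intrinsic state selected against the
#' unconstrained repertoire; negative raw values are clamped to zero (kept
#' in `phi_raw`), and a support mismatch between the repertoire and its
#' partitioned version yields `Inf`.
#'
#' @inheritParams partitioned_repertoire
#' @param rep optionally, the precomputed full `repertoire`.
#' @return list (class `partitioned_score`): `partition`, `phi`, `phi_raw`,
#'   `normalization`, `normalized_phi`.
#' @export
phi_given_partition <- function(U, m, Z, theta,
                                direction = c("effect", "cause"),
                                rep = NULL,
                                cache = new.env(parent = emptyenv())) {
  direction <- match.arg(direction)
  if (is.null(rep)) rep <- repertoire(U, m, Z, direction)
  if (rep$empty) {
    sc <- list(partition = theta, phi = 0, phi_raw = 0,
               normalization = normalization_factor(theta), normalized_phi = 0)
    class(sc) <- "partitioned_score"
    return(sc)
  }
  esys <- eigendecompose(rep$state)
  group <- .intrinsic_group(esys)
  prep <- partitioned_repertoire(U, m, Z, theta, direction, cache)
  phi_raw <- if (is.null(prep)) Inf else .phi_at_state(group, eigendecompose(prep))
  nf <- normalization_factor(theta)
  sc <- list(partition = theta, phi = max(phi_raw, 0), phi_raw = phi_raw,
             normalization = nf,
             normalized_phi = max(phi_raw, 0) / nf)
  class(sc) <- "partitioned_score"
  sc
}

#' @export
print.partitioned_score <- function(x, digits = 6, ...) {
  cat(format(x$partition), ": phi =", round(x$phi, digits),
      "(norm", x$normalization, "->", round(x$normalized_phi, digits), ")\n")
  invisible(x)
}

#' Minimum information partition (MIP) search
#'
#' Exhaustive search over all disintegrating partitions of (`m$units`, `Z`),
#' minimizing the normalized phi; the winner is reported with its
#' unnormalized phi. Ties in normalized phi are broken deterministically by
#' canonical enumeration order and recorded.
#'
#' @inheritParams phi_given_partition
#' @param tie_tol tolerance for tie detection.
#' @return a `partitioned_score` with extra fields `repertoire`,
#'   `intrinsic` (leading eigengroup of the repertoire: `p`, `vectors`) and
#'   `ties` (other partitions with equal normalized phi).
#' @export
find_mip <- function(U, m, Z, direction = c("effect", "cause"),
                     cache = new.env(parent = emptyenv()), tie_tol = 1e-9) {
  direction <- match.arg(direction)
  Z <- as.character(Z)
  rep <- repertoire(U, m, Z, direction)
  thetas <- enumerate_partitions(m$units, Z)
  scores <- lapply(thetas, function(th)
    phi_given_partition(U, m, Z, th, direction, rep = rep, cache = cache))
  nphi <- vapply(scores, `[[`, 0, "normalized_phi")
  best_i <- which.min(nphi) # first minimum in canonical order
  best <- scores[[best_i]]
  ties <- which(abs(nphi - nphi[best_i]) <= tie_tol)
  best$ties <- lapply(scores[setdiff(ties, best_i)], `[[`, "partition")
  best$repertoire <- rep
  best$intrinsic <- if (rep$empty) NULL else .intrinsic_group(eigendecompose(rep$state))
  best
}
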