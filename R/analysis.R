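# Purview optimization, distinctions, and compositional unfolding of a
# system's cause-effect structure.
#
# phi(m) maximizes phi(m, Z) over all nonempty purviews Z of the register.
# Ties across purview sizes are resolved toward the larger purview; ties at
# equal size are broken by canonical subset order and recorded. Unfolding
# iterates every nonempty mechanism subset: effect-side mechanism states are
# reduced from the input state, cause-side states from the updated state.

#' Maximally irreducible cause or effect of a mechanism
#'
#' Exhaustively maximizes the MIP-evaluated integrated information over all
#' nonempty purviews of the register.
#'
#' @param U a [qchannel].
#' @param m a [mechanism].
#' @param direction `"effect"`, `"cause"`, or `"both"` (min of the two
#'   sides, computed from the same mechanism state; meaningful for
#'   self-adjoint channels and the identity-channel constraint analysis).
#' @param cache optional memoization environment shared across calls with
#'   the same mechanism state.
#' @return object of class `distinction`: fields `mechanism`, `direction`,
#'   `phi`, `ii`, `purview`, `intrinsic_state`, `mip`, `ties` (co-optimal
#'   purviews), and for `direction = "both"` also `phi_e`, `phi_c` and the
#'   per-side records.
#' @export
phi_mechanism <- function(U, m, direction = c("effect", "cause", "both"),
                          cache = new.env(parent = emptyenv())) {
  direction <- match.arg(direction)
  if (direction == "both") {
    de <- phi_mechanism(U, m, "effect", cache)
    dc <- phi_mechanism(U, m, "cause", cache)
    d <- if (de$phi <= dc$phi) de else dc
    d$phi_e <- de$phi
    d$phi_c <- dc$phi
    d$effect <- de
    d$cause <- dc
    d$direction <- "both"
    d$phi <- min(de$phi, dc$phi)
    return(d)
  }
  purviews <- unit_subsets(U$units)
  mips <- lapply(purviews, function(Z) find_mip(U, m, Z, direction, cache))
  phis <- vapply(mips, `[[`, 0, "phi")
  sizes <- vapply(purviews, length, 1L)
  tol <- 1e-9
  top <- which(phis >= max(phis) - tol)
  best_i <- top[order(-sizes[top], top)][1] # larger purview wins ties
  ties <- setdiff(top[sizes[top] == sizes[best_i]], best_i)
  best <- mips[[best_i]]
  structure(list(
    mechanism = m,
    direction = direction,
    phi = best$phi,
    ii = if (best$repertoire$empty) 0
         else qid(best$repertoire$state, maximally_mixed(best$repertoire$purview))$value,
    purview = purviews[[best_i]],
    intrinsic_state = best$intrinsic,
    repertoire = best$repertoire,
    mip = best$partition,
    mip_ties = best$ties,
    ties = lapply(ties, function(i)
      list(purview = purviews[[i]], intrinsic_state = mips[[i]]$intrinsic)),
    all_purviews = Map(function(Z, ph) list(purview = Z, phi = ph),
                       purviews, phis)
  ), class = "distinction")
}

#' @export
print.distinction <- function(x, digits = 4, ...) {
  n <- length(x$purview)
  lab <- if (is.null(x$intrinsic_state)) "-"
         else state_label(x$intrinsic_state$vectors, n)
  cat(sprintf("<distinction> %s of [%s]: phi = %s over [%s] = %s%s\n",
              x$direction, paste(x$mechanism$units, collapse = " "),
              format(round(x$phi, digits)),
              paste(x$purview, collapse = " "), lab,
              if (length(x$ties)) sprintf(" (+%d tied purview(s))", length(x$ties)) else ""))
  invisible(x)
}

#' Unfold the cause-effect structure of a system transition
#'
#' In `"transition"` mode, evaluates the intrinsic effects of every nonempty
#' mechanism of the input state and the intrinsic causes of every nonempty
#' mechanism of the updated state. In `"self"` mode the channel is the
#' identity and cause and effect coincide: each mechanism's record is a
#' constraint of the state on itself, reported once with side
#' `"constraint"`.
#'
#' @param U a [qchannel]; ignored (replaced by the identity) in self mode.
#' @param state the system state at t, a [qstate].
#' @param mode `"transition"` or `"self"`.
#' @param phi_tol mechanisms with phi below this are reported in the
#'   zero-phi list rather than as distinctions.
#' @return object of class `ces`: `records` (all mechanism records, each
#'   with a `side` field), `state_t`, `state_t1`, `channel`, `mode`.
#' @export
unfold <- function(U, state, mode = c("transition", "self"), phi_tol = 1e-9) {
  mode <- match.arg(mode)
  stopifnot(inherits(state, "qstate"))
  if (mode == "self") U <- identity_channel(state$units)
  stopifnot(inherits(U, "qchannel"))
  if (!setequal(U$units, state$units))
    stop("state register does not match channel register")
  state <- permute_units(state, U$units)
  state_t1 <- apply_channel(U, state)
  subsets <- unit_subsets(U$units)
  records <- list()
  # per-part repertoires depend only on the part's units (all mechanism
  # states are reductions of the same system state), so one cache can be
  # shared across mechanisms on each side
  if (mode == "transition") {
    cache_e <- new.env(parent = emptyenv())
    cache_c <- new.env(parent = emptyenv())
    for (S in subsets) {
      d <- phi_mechanism(U, mechanism(state, S), "effect", cache = cache_e)
      d$side <- "effect"
      records[[length(records) + 1]] <- d
    }
    for (S in subsets) {
      d <- phi_mechanism(U, mechanism(state_t1, S), "cause", cache = cache_c)
      d$side <- "cause"
      records[[length(records) + 1]] <- d
    }
  } else {
    cache_s <- new.env(parent = emptyenv())
    for (S in subsets) {
      d <- phi_mechanism(U, mechanism(state, S), "effect", cache = cache_s)
      d$side <- "constraint"
      records[[length(records) + 1]] <- d
    }
  }
  structure(list(records = records, state_t = state, state_t1 = state_t1,
                 channel = U, mode = mode, phi_tol = phi_tol),
            class = "ces")
}

#' Distinctions (positive-phi records) of a cause-effect structure
#' @param ces a `ces` object from [unfold].
#' @param positive if `FALSE`, return all records including reducible ones.
#' @return list of `distinction` objects.
#' @export
distinctions <- function(ces, positive = TRUE) {
  stopifnot(inherits(ces, "ces"))
  if (!positive) return(ces$records)
  Filter(function(d) d$phi > ces$phi_tol, ces$records)
}

#' Tabulate a cause-effect structure
#' @param x a `ces` object.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data frame with one row per mechanism record.
#' @export
as.data.frame.ces <- function(x, row.names = NULL, optional = FALSE, ...) {
  rows <- lapply(x$records, function(d) {
    data.frame(
      side = d$side,
      mechanism = paste(d$mechanism$units, collapse = ""),
      mechanism_state = if (is_pure(d$mechanism$state))
        state_label(eigendecompose(d$mechanism$state)$vectors[, 1, drop = FALSE],
                    length(d$mechanism$units)) else "mixed",
      order = length(d$mechanism$units),
      phi = d$phi,
      ii = d$ii,
      purview = paste(d$purview, collapse = ""),
      intrinsic_state = if (is.null(d$intrinsic_state)) NA_character_
        else state_label(d$intrinsic_state$vectors, length(d$purview)),
      n_purview_ties = length(d$ties),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' @export
print.ces <- function(x, digits = 4, ...) {
  cat(sprintf("<cause-effect structure> mode = %s, register [%s]\n",
              x$mode, paste(x$channel$units, collapse = " ")))
  df <- as.data.frame(x)
  df$phi <- round(df$phi, digits)
  df$ii <- round(df$ii, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Histogram of positive-phi mechanism orders
#' @param ces a `ces` object.
#' @param side which side(s) to count; defaults to all present.
#' @return integer vector of length n (register size): count of positive-phi
#'   mechanisms of each order.
#' @export
order_histogram <- function(ces, side = NULL) {
  n <- length(ces$channel$units)
  ds <- distinctions(ces)
  if (!is.null(side)) ds <- Filter(function(d) d$side %in% side, ds)
  counts <- integer(n)
  for (d in ds) {
    k <- length(d$mechanism$units)
    counts[k] <- counts[k] + 1L
  }
  counts
}

#' Compare two cause-effect structures
#'
#' Reports per-order counts of positive-phi mechanisms for each structure
#' and phi deltas for mechanism records present in both (matched by side
#' and mechanism units).
#'
#' @param cs1,cs2 `ces` objects over registers of equal size.
#' @return list with `orders1`, `orders2` (per-side order histograms) and
#'   `delta` (data frame of phi differences), class `ces_diff`.
#' @export
compare_structures <- function(cs1, cs2) {
  stopifnot(inherits(cs1, "ces"), inherits(cs2, "ces"))
  if (length(cs1$channel$units) != length(cs2$channel$units))
    stop("structures must have the same register size")
  sides1 <- unique(vapply(cs1$records, `[[`, "", "side"))
  sides2 <- unique(vapply(cs2$records, `[[`, "", "side"))
  orders1 <- sapply(sides1, function(s) order_histogram(cs1, s), simplify = FALSE)
  orders2 <- sapply(sides2, function(s) order_histogram(cs2, s), simplify = FALSE)
  key <- function(d) paste(d$side, paste(d$mechanism$units, collapse = ""))
  k1 <- vapply(cs1$records, key, "")
  k2 <- vapply(cs2$records, key, "")
  shared <- intersect(k1, k2)
  delta <- do.call(rbind, lapply(shared, function(k) {
    d1 <- cs1$records[[match(k, k1)]]
    d2 <- cs2$records[[match(k, k2)]]
    data.frame(record = k, phi1 = d1$phi, phi2 = d2$phi,
               delta = d1$phi - d2$phi, stringsAsFactors = FALSE)
  }))
  delta <- delta[abs(delta$delta) > 1e-9 | delta$phi1 > 1e-9 | delta$phi2 > 1e-9, ]
  structure(list(orders1 = orders1, orders2 = orders2, delta = delta),
            class = "ces_diff")
}

#' @export
print.ces_diff <- function(x, ...) {
  cat("positive-phi mechanism counts per order\n  structure 1:\n")
  for (s in names(x$orders1))
    cat("   ", s, ":", paste(x$orders1[[s]], collapse = " "), "\n")
  cat("  structure 2:\n")
  for (s in names(x$orders2))
    cat("   ", s, ":", paste(x$orders2[[s]], collapse = " "), "\n")
  if (!is.null(x$delta) && nrow(x$delta)) {
    cat("phi deltas on shared records:\n")
    print(x$delta, row.names = FALSE)
  } else cat("no phi differences on shared records\n")
  invisible(x)
}
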