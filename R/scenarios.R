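# Canonical analysis scenarios, randomized instance generators, and JSON
# serialization helpers for reports and the command-line interface.

.scenario_table <- function() {
  list(
    copyxor_10 = list(
      description = "reversible COPY-XOR gate (classical truth table embedded as a permutation unitary) on basis input 10",
      register = c("A", "B"),
      state = "10",
      channel = function(u) from_truth_table(
        c("00" = "00", "01" = "01", "10" = "11", "11" = "10"), u),
      mode = "transition"),
    cnot_10 = list(
      description = "CNOT on computational-basis input 10 (classical regime)",
      register = c("A", "B"), state = "10",
      channel = function(u) named_gate("CNOT", u), mode = "transition"),
    cnot_minusplus = list(
      description = "CNOT on Hadamard-basis input -+ (control/target roles reversed)",
      register = c("A", "B"), state = "-+",
      channel = function(u) named_gate("CNOT", u), mode = "transition"),
    cnot_plus0 = list(
      description = "CNOT on +0: Bell-state creation; only second-order mechanisms",
      register = c("A", "B"), state = "+0",
      channel = function(u) named_gate("CNOT", u), mode = "transition"),
    cnot_0plus = list(
      description = "CNOT on 0+: no interaction; only first-order mechanisms",
      register = c("A", "B"), state = "0+",
      channel = function(u) named_gate("CNOT", u), mode = "transition"),
    cnot_mixed = list(
      description = "CNOT on the even classical mixture of 00 and 11",
      register = c("A", "B"),
      state = c("00" = 0.5, "11" = 0.5),
      channel = function(u) named_gate("CNOT", u), mode = "transition"),
    icnot_ghz = list(
      description = "identity-extended CNOT (I on the first qubit) applied to a GHZ state: the mixed-state scenario embedded in a pure tripartite state",
      register = c("A", "B", "C"), state = "ghz",
      channel = function(u) named_gate("I⊗CNOT", u), mode = "transition"),
    classical_self = list(
      description = "identity constraint analysis of a classical basis state",
      register = c("A", "B", "C"), state = "000",
      channel = function(u) identity_channel(u), mode = "self"),
    ghz_self = list(
      description = "identity constraint analysis of the GHZ state: third-order constraint only",
      register = c("A", "B", "C"), state = "ghz",
      channel = function(u) identity_channel(u), mode = "self"),
    w_self = list(
      description = "identity constraint analysis of the W state: constraints of all orders",
      register = c("A", "B", "C"), state = "w",
      channel = function(u) identity_channel(u), mode = "self")
  )
}

#' Names of the built-in analysis scenarios
#' @return character vector.
#' @export
scenario_names <- function() names(.scenario_table())

#' Load a built-in scenario (or a scenario description list)
#'
#' @param name a scenario name from [scenario_names()], or a list with
#'   fields `register`, `state`, `channel` (gate name, truth table, or
#'   matrix) and `mode`.
#' @return list of class `scenario` with a parsed [qstate] and [qchannel].
#' @export
load_scenario <- function(name) {
  if (is.character(name)) {
    tab <- .scenario_table()
    if (!name %in% names(tab))
      stop("unknown scenario '", name, "'; see scenario_names()")
    sc <- tab[[name]]
    sc$name <- name
  } else if (is.list(name)) {
    sc <- name
    if (is.null(sc$name)) sc$name <- "custom"
    if (is.character(sc$channel)) {
      gate <- sc$channel
      sc$channel <- function(u) named_gate(gate, u)
    } else if (is.matrix(sc$channel)) {
      mat <- sc$channel
      sc$channel <- function(u) qchannel(mat, u)
    }
    if (is.null(sc$mode)) sc$mode <- "transition"
  } else stop("scenario must be a name or a description list")
  sc$state <- parse_state(sc$state, sc$register)
  sc$channel <- sc$channel(sc$register)
  class(sc) <- "scenario"
  sc
}

#' Run a scenario end to end
#' @param sc a scenario name or `scenario` object.
#' @return the [unfold] result (`ces`).
#' @export
run_scenario <- function(sc) {
  if (!inherits(sc, "scenario")) sc <- load_scenario(sc)
  unfold(sc$channel, sc$state, sc$mode)
}

## ---- randomized instances --------------------------------------------------

#' Haar-random unitary matrix
#'
#' QR decomposition of a complex Gaussian matrix with phase-corrected
#' diagonal. Uses the current RNG state.
#'
#' @param d matrix dimension.
#' @return a `d x d` complex unitary matrix.
#' @export
random_haar_unitary <- function(d) {
  G <- matrix(complex(real = stats::rnorm(d * d),
                      imaginary = stats::rnorm(d * d)) / sqrt(2), d, d)
  qr_ <- qr(G)
  Q <- qr.Q(qr_)
  R <- qr.R(qr_)
  ph <- diag(R) / Mod(diag(R))
  Q %*% diag(ph, d)
}

#' Random density matrix (eigenvalues uniform on the simplex, Haar basis)
#' @param d dimension.
#' @return a `d x d` complex density matrix.
#' @export
random_density_matrix <- function(d) {
  ev <- stats::rexp(d)
  ev <- ev / sum(ev)
  V <- random_haar_unitary(d)
  V %*% diag(ev, d) %*% Conj(t(V))
}

#' Reproducible random scenario
#'
#' @param seed integer seed; the instance is fully determined by it.
#' @param n_qubits 2 or 3.
#' @param kind `"haar_unitary"`, `"permutation"`, `"product_state"` (random
#'   pure product state under a Haar unitary), or `"random_mixed"`.
#' @return a `scenario` object.
#' @export
random_instance <- function(seed, n_qubits = 2,
                            kind = c("haar_unitary", "permutation",
                                     "product_state", "random_mixed")) {
  kind <- match.arg(kind)
  stopifnot(n_qubits %in% c(2, 3))
  set.seed(seed)
  units <- LETTERS[seq_len(n_qubits)]
  d <- 2^n_qubits
  chan <- switch(kind,
    permutation = {
      perm <- sample(d)
      P <- matrix(0, d, d)
      for (i in seq_len(d)) P[perm[i], i] <- 1
      qchannel(P, units)
    },
    qchannel(random_haar_unitary(d), units))
  st <- switch(kind,
    random_mixed = qstate(random_density_matrix(d), units, validate = FALSE),
    product_state = {
      kets <- lapply(seq_len(n_qubits), function(i) {
        v <- complex(real = stats::rnorm(2), imaginary = stats::rnorm(2))
        v <- v / sqrt(sum(Mod(v)^2))
        qstate(outer(v, Conj(v)), units[i], validate = FALSE)
      })
      compose(kets)
    },
    { # basis state for haar_unitary / permutation kinds
      b <- sample(0:(d - 1), 1)
      parse_state(paste(.bits(b, n_qubits), collapse = ""), units)
    })
  structure(list(name = sprintf("random_%s_seed%d", kind, seed),
                 description = "randomized property-test instance",
                 register = units, state = st, channel = chan,
                 mode = "transition", seed = seed, kind = kind),
            class = "scenario")
}

## ---- JSON ------------------------------------------------------------------

# complex matrix -> nested arrays of [re, im] pairs
.cplx_to_json <- function(m) {
  lapply(seq_len(nrow(m)), function(i)
    lapply(seq_len(ncol(m)), function(j) c(Re(m[i, j]), Im(m[i, j]))))
}

#' Serialize a repertoire, distinction or cause-effect structure to JSON
#'
#' Matrices are emitted as nested arrays of `[re, im]` pairs.
#'
#' @param x a `repertoire`, `distinction` or `ces` object.
#' @param path optional file to write to.
#' @return JSON string (invisibly, if `path` given).
#' @export
to_json <- function(x, path = NULL) {
  obj <- if (inherits(x, "repertoire")) {
    list(direction = x$direction,
         mechanism = x$mechanism_units,
         purview = x$purview,
         factorization = lapply(x$factorization, identity),
         empty = x$empty,
         matrix = if (x$empty) NULL else .cplx_to_json(x$state$matrix))
  } else if (inherits(x, "distinction")) {
    list(side = x$side, direction = x$direction,
         mechanism = x$mechanism$units,
         phi = round(x$phi, 6), ii = round(x$ii, 6),
         purview = x$purview,
         intrinsic_state = if (is.null(x$intrinsic_state)) NULL else list(
           eigenvalue = x$intrinsic_state$p,
           degenerate = ncol(x$intrinsic_state$vectors) > 1,
           label = state_label(x$intrinsic_state$vectors, length(x$purview)),
           vectors = .cplx_to_json(x$intrinsic_state$vectors)),
         mip = format(x$mip),
         n_purview_ties = length(x$ties))
  } else if (inherits(x, "ces")) {
    list(mode = x$mode,
         register = x$channel$units,
         settings = list(tolerance = .qphi_tol,
                         degeneracy_tolerance = .qphi_deg_tol,
                         normalization = "severed mechanism-purview unit pairs"),
         records = lapply(x$records, function(d)
           jsonlite::parse_json(to_json(d))))
  } else stop("unsupported object")
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
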