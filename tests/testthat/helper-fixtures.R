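# Shared fixtures: all built in code, no stored data.

ket0 <- c(1, 0)
ket1 <- c(0, 1)
ketp <- c(1, 1) / sqrt(2)
ketm <- c(1, -1) / sqrt(2)

dm <- function(v) outer(as.complex(v), Conj(as.complex(v)))

kron_all <- function(...) Reduce(kronecker, list(...))

cnot_matrix <- matrix(c(1, 0, 0, 0,
                        0, 1, 0, 0,
                        0, 0, 0, 1,
                        0, 0, 1, 0), 4, 4, byrow = TRUE)

copyxor_table <- c("00" = "00", "01" = "01", "10" = "11", "11" = "10")

cnot_AB <- function() named_gate("CNOT", c("A", "B"))

bell_plus <- function(units = c("C", "D")) parse_state("bell", units)

w_state <- function(units = c("A", "B", "C")) parse_state("w", units)

ghz_state <- function(units = c("A", "B", "C")) parse_state("ghz", units)

# matrix comparison with tolerance
expect_mat_equal <- function(actual, expected, tol = 1e-8) {
  expect_lt(max(Mod(as.matrix(actual) - as.matrix(expected))), tol)
}

# bit utilities (kept local so tests do not reach into package internals)
bits_of <- function(i, n) (i %/% 2^((n - 1):0)) %% 2

basis_string <- function(i, n) paste(bits_of(i, n), collapse = "")

# all 2-bit reversible gates as truth tables (the 24 permutations of 4 states)
all_two_bit_permutations <- function() {
  states <- c("00", "01", "10", "11")
  perms <- list()
  for (a in 1:4) for (b in setdiff(1:4, a)) for (cc in setdiff(1:4, c(a, b))) {
    d <- setdiff(1:4, c(a, b, cc))
    perms[[length(perms) + 1]] <- stats::setNames(states[c(a, b, cc, d)], states)
  }
  perms
}

# signature of a disintegrating partition, for set comparisons
theta_signature <- function(theta) {
  sig <- vapply(theta$parts, function(p)
    paste0(paste(sort(p$m), collapse = ""), ":", paste(sort(p$z), collapse = "")), "")
  paste(sort(sig), collapse = "|")
}
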