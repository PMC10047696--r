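# Purview optimization, unfolding, and structure comparison.

test_that("purview maximization reproduces the CNOT pipeline", {
  U <- cnot_AB()
  s10 <- parse_state("10", c("A", "B"))
  # first-order control: 1 ibit onto the copied output
  d1 <- phi_mechanism(U, mechanism(s10, "A"), "effect")
  expect_equal(d1$phi, 1, tolerance = 1e-9)
  expect_identical(d1$purview, "A")
  expect_identical(state_label(d1$intrinsic_state$vectors, 1), "1")
  # second-order: tie across purview sizes resolved to the larger purview
  d2 <- phi_mechanism(U, mechanism(s10), "effect")
  expect_equal(d2$phi, 1, tolerance = 1e-9)
  expect_identical(d2$purview, c("A", "B"))
  expect_identical(state_label(d2$intrinsic_state$vectors, 2), "11")
  phis <- vapply(d2$all_purviews, `[[`, 0, "phi")
  names(phis) <- vapply(d2$all_purviews,
                        function(p) paste(p$purview, collapse = ""), "")
  expect_equal(unname(phis["B"]), 1, tolerance = 1e-9) # the tied smaller purview
  # cause of the second output unit: 0.5 ibit with tied basis states
  out <- apply_channel(U, s10)
  d3 <- phi_mechanism(U, mechanism(out, "B"), "cause")
  expect_equal(d3$phi, 0.5, tolerance = 1e-9)
  expect_identical(d3$purview, c("A", "B"))
  expect_true(ncol(d3$intrinsic_state$vectors) == 2) # degenerate 10/01 space
  # mixed input: effect lands on the second output qubit in state 0
  mixed <- parse_state(c("00" = 0.5, "11" = 0.5), c("A", "B"))
  d4 <- phi_mechanism(U, mechanism(mixed), "effect")
  expect_equal(d4$phi, 1, tolerance = 1e-9)
  expect_identical(d4$purview, "B")
  expect_identical(state_label(d4$intrinsic_state$vectors, 1), "0")
  phis4 <- vapply(d4$all_purviews, `[[`, 0, "phi")
  names(phis4) <- vapply(d4$all_purviews,
                         function(p) paste(p$purview, collapse = ""), "")
  expect_equal(unname(phis4["A"]), 0, tolerance = 1e-9) # first output undetermined
})

test_that("direction = both reports the minimum of the two sides", {
  I2 <- identity_channel(c("A", "B"))
  d <- phi_mechanism(I2, mechanism(bell_plus(c("A", "B"))), "both")
  expect_equal(d$phi, min(d$phi_e, d$phi_c), tolerance = 1e-12)
  expect_equal(d$phi_e, d$phi_c, tolerance = 1e-9) # identity is self-adjoint
})

test_that("unfolding the classical-input CNOT transition matches the gate logic", {
  ces <- unfold(cnot_AB(), parse_state("10", c("A", "B")), "transition")
  df <- as.data.frame(ces)
  eff <- df[df$side == "effect", ]
  expect_equal(eff$phi[eff$mechanism == "A"], 1, tolerance = 1e-9)
  expect_equal(eff$phi[eff$mechanism == "B"], 0, tolerance = 1e-9)
  expect_equal(eff$phi[eff$mechanism == "AB"], 1, tolerance = 1e-9)
  expect_identical(eff$intrinsic_state[eff$mechanism == "AB"], "11")
  cau <- df[df$side == "cause", ]
  expect_equal(sort(cau$phi), c(0.5, 1, 1), tolerance = 1e-9)
  # three irreducible causes, two irreducible effects
  expect_length(distinctions(ces), 5)
})

test_that("identity self-analysis separates GHZ-type from W-type structure", {
  ghz <- unfold(NULL, ghz_state(), "self")
  w <- unfold(NULL, w_state(), "self")
  expect_identical(order_histogram(ghz), c(0L, 0L, 1L))
  expect_identical(order_histogram(w), c(3L, 3L, 1L))
  # classical basis states only constrain first order
  cl <- unfold(NULL, parse_state("000", c("A", "B", "C")), "self")
  expect_identical(order_histogram(cl), c(3L, 0L, 0L))
  diff <- compare_structures(ghz, w)
  expect_identical(diff$orders1$constraint, c(0L, 0L, 1L))
  expect_identical(diff$orders2$constraint, c(3L, 3L, 1L))
  # self-comparison is empty
  self_diff <- compare_structures(ghz, ghz)
  expect_true(is.null(self_diff$delta) || nrow(self_diff$delta) == 0 ||
              all(abs(self_diff$delta$delta) < 1e-12))
})

test_that("an identity-extended spectator qubit preserves subsystem distinctions", {
  # embed the mixed-state two-qubit transition in a pure tripartite state:
  # tracing the first GHZ qubit leaves the classical 00/11 mixture feeding
  # the gate on the remaining pair
  sc <- load_scenario("icnot_ghz")
  st <- sc$state
  out <- apply_channel(sc$channel, st)
  expect_mat_equal(partial_trace(st, c("B", "C"))$matrix,
                   diag(c(0.5, 0, 0, 0.5)))
  d_eff <- phi_mechanism(sc$channel, mechanism(st, c("B", "C")), "effect")
  expect_equal(d_eff$phi, 1, tolerance = 1e-9)
  expect_identical(d_eff$purview, "C")
  expect_identical(state_label(d_eff$intrinsic_state$vectors, 1), "0")
  d_cau <- phi_mechanism(sc$channel, mechanism(out, "C"), "cause")
  expect_equal(d_cau$phi, 0.5, tolerance = 1e-9)
  expect_identical(d_cau$purview, c("B", "C"))
  # additional distinctions spanning all three qubits appear
  d_full <- phi_mechanism(sc$channel, mechanism(st), "effect")
  expect_gt(d_full$phi, 0)
  expect_identical(d_full$purview, c("A", "B", "C"))
})

test_that("Bell-creating and non-interacting transitions differ at second order", {
  bell <- unfold(cnot_AB(), parse_state("+0", c("A", "B")), "transition")
  noint <- unfold(cnot_AB(), parse_state("0+", c("A", "B")), "transition")
  expect_identical(order_histogram(bell, "effect"), c(0L, 1L))
  expect_identical(order_histogram(bell, "cause"), c(0L, 1L))
  expect_identical(order_histogram(noint, "effect"), c(2L, 0L))
  expect_identical(order_histogram(noint, "cause"), c(2L, 0L))
  # zero-phi mechanisms are retained in the report, not dropped
  expect_length(bell$records, 6)
  expect_length(distinctions(bell, positive = FALSE), 6)
})
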