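# Quantum intrinsic difference and quantum relative entropy.

test_that("QID matches hand-computed values", {
  expect_equal(qid(parse_state("1", "A"), maximally_mixed("A"))$value, 1)
  mix <- qstate(diag(c(0, 0.5, 0.5, 0)), c("A", "B"))
  iv <- qid(mix, maximally_mixed(c("A", "B")))
  expect_equal(iv$value, 0.5, tolerance = 1e-12)
  expect_true(iv$optimizer$is_degenerate)
  expect_equal(ncol(iv$optimizer$vectors), 2)
  # identical arguments
  set.seed(13)
  for (i in 1:5) {
    r <- qstate(random_density_matrix(4), c("A", "B"), validate = FALSE)
    expect_equal(qid(r, r)$value, 0, tolerance = 1e-9)
  }
})

test_that("quantum relative entropy matches closed forms", {
  mix <- qstate(diag(c(0, 0.5, 0.5, 0)), c("A", "B"))
  expect_equal(quantum_relative_entropy(mix, maximally_mixed(c("A", "B"))), 1,
               tolerance = 1e-12)
  expect_equal(quantum_relative_entropy(parse_state("+", "A"),
                                        maximally_mixed("A")), 1,
               tolerance = 1e-12)
  r <- qstate(random_density_matrix(4), c("A", "B"), validate = FALSE)
  expect_equal(quantum_relative_entropy(r, r), 0, tolerance = 1e-9)
  # support mismatch is reported as +Inf, not clipped
  expect_equal(qid(parse_state("0", "A"), parse_state("1", "A"))$value, Inf)
})

test_that("QID equals the relative entropy on pure states and is subadditive", {
  set.seed(17)
  units <- c("A", "B")
  for (i in 1:20) {
    sig <- qstate(random_density_matrix(4), units, validate = FALSE)
    # pure rho: a single spectral term, so QID and S coincide
    v <- random_haar_unitary(4)[, 1]
    pure <- qstate(outer(v, Conj(v)), units, validate = FALSE)
    expect_equal(qid(pure, sig)$value, quantum_relative_entropy(pure, sig),
                 tolerance = 1e-8)
    # subadditivity over tensor products
    r1 <- random_density_matrix(2); r2 <- random_density_matrix(2)
    s1 <- random_density_matrix(2); s2 <- random_density_matrix(2)
    q12 <- qid(qstate(kronecker(r1, r2), units, validate = FALSE),
               qstate(kronecker(s1, s2), units, validate = FALSE))$value
    q1 <- qid(qstate(r1, "A", validate = FALSE),
              qstate(s1, "A", validate = FALSE))$value
    q2 <- qid(qstate(r2, "B", validate = FALSE),
              qstate(s2, "B", validate = FALSE))$value
    expect_lte(q12, q1 + q2 + 1e-9)
  }
})

test_that("QID agrees with the classical intrinsic difference on diagonals", {
  set.seed(19)
  for (i in 1:20) {
    p <- stats::rexp(4); p <- p / sum(p)
    q <- stats::rexp(4); q <- q / sum(q)
    rho <- qstate(diag(p), c("A", "B"), validate = FALSE)
    sig <- qstate(diag(q), c("A", "B"), validate = FALSE)
    expect_equal(qid(rho, sig)$value, classical_id(p, q)$value,
                 tolerance = 1e-9)
    expect_equal(quantum_relative_entropy(rho, sig), classical_kld(p, q),
                 tolerance = 1e-9)
  }
})

test_that("QID is invariant under a joint change of basis", {
  set.seed(23)
  for (i in 1:10) {
    rho <- qstate(random_density_matrix(4), c("A", "B"), validate = FALSE)
    sig <- qstate(random_density_matrix(4), c("A", "B"), validate = FALSE)
    v0 <- qid(rho, sig)$value
    V <- random_haar_unitary(4)
    rho2 <- qstate(V %*% rho$matrix %*% Conj(t(V)), c("A", "B"), validate = FALSE)
    sig2 <- qstate(V %*% sig$matrix %*% Conj(t(V)), c("A", "B"), validate = FALSE)
    expect_equal(qid(rho2, sig2)$value, v0, tolerance = 1e-8)
  }
})

test_that("against the mixed state the optimizer is the leading eigenvector", {
  set.seed(29)
  for (i in 1:20) {
    rho <- qstate(random_density_matrix(4), c("A", "B"), validate = FALSE)
    iv <- qid(rho, maximally_mixed(c("A", "B")))
    es <- eigendecompose(rho)
    expect_equal(iv$optimizer$eigenvalue, es$values[1], tolerance = 1e-9)
  }
})

test_that("intrinsic information reproduces the CNOT pipeline values", {
  U <- cnot_AB()
  iv <- intrinsic_information(U, mechanism(parse_state("10", c("A", "B"))),
                              c("A", "B"), "effect")
  expect_equal(iv$value, 2, tolerance = 1e-9)
  expect_identical(state_label(iv$optimizer$vectors, 2), "11")
  # a lone XOR input carries no intrinsic effect information
  iv0 <- intrinsic_information(U, mechanism(parse_state("10", c("A", "B")), "B"),
                               c("A", "B"), "effect")
  expect_equal(iv0$value, 0, tolerance = 1e-9)
  # Bell creation: 2 ibits onto the entangled purview
  ivb <- intrinsic_information(U, mechanism(parse_state("+0", c("A", "B"))),
                               c("A", "B"), "effect")
  expect_equal(ivb$value, 2, tolerance = 1e-9)
  expect_identical(state_label(ivb$optimizer$vectors, 2), "B+")
})
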