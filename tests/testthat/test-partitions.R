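# Disintegrating partitions, partitioned repertoires, phi and the MIP
# search.

# Independent brute-force oracle: assign every mechanism and purview unit a
# block id in 1..k, construct the induced pairs, filter by the defining
# constraints, and deduplicate by canonical signature.
brute_force_partitions <- function(M, Z) {
  nm <- length(M); nz <- length(Z)
  total <- nm + nz
  sigs <- character(0)
  for (k in 2:(nm + nz)) {
    grid <- expand.grid(rep(list(seq_len(k)), total))
    for (r in seq_len(nrow(grid))) {
      lab <- as.integer(grid[r, ])
      if (length(unique(lab)) != k) next
      parts <- lapply(seq_len(k), function(b)
        list(m = M[which(lab[seq_len(nm)] == b)],
             z = Z[which(lab[nm + seq_len(nz)] == b)]))
      # constraints: no empty-empty part; whole mechanism -> empty purview
      if (any(vapply(parts, function(p) length(p$m) == 0 && length(p$z) == 0, TRUE))) next
      if (any(vapply(parts, function(p)
        length(p$m) == nm && length(p$z) > 0, TRUE))) next
      sig <- paste(sort(vapply(parts, function(p)
        paste0(paste(sort(p$m), collapse = ""), ":",
               paste(sort(p$z), collapse = "")), "")), collapse = "|")
      sigs <- c(sigs, sig)
    }
  }
  unique(sigs)
}

test_that("partition enumeration is complete and duplicate-free", {
  # single-pair case: exactly the total cut
  th1 <- enumerate_partitions("A", "C")
  expect_length(th1, 1)
  expect_identical(theta_signature(th1[[1]]), ":C|A:")
  # 2x2 case against the brute-force oracle
  th <- enumerate_partitions(c("A", "B"), c("C", "D"))
  sigs <- vapply(th, theta_signature, "")
  expect_false(anyDuplicated(sigs) > 0)
  expect_setequal(sigs, brute_force_partitions(c("A", "B"), c("C", "D")))
  # includes the named examples
  expect_true("A:C|B:D" %in% sigs)
  expect_true("A:D|B:C" %in% sigs)
  expect_true("A:|B:CD" %in% sigs)
  expect_true(":CD|AB:" %in% sigs) # total cut
  # 1x2 and 2x1 cases
  expect_setequal(vapply(enumerate_partitions("A", c("C", "D")),
                         theta_signature, ""),
                  brute_force_partitions("A", c("C", "D")))
  expect_setequal(vapply(enumerate_partitions(c("A", "B"), "C"),
                         theta_signature, ""),
                  brute_force_partitions(c("A", "B"), "C"))
  # single-unit mechanisms only produce total cuts
  for (t in enumerate_partitions("A", c("C", "D"))) {
    withm <- Filter(function(p) length(p$m) > 0, t$parts)
    expect_true(all(vapply(withm, function(p) length(p$z) == 0, TRUE)))
  }
  # every partition passes the structural invariants
  for (t in th) {
    ms <- unlist(lapply(t$parts, `[[`, "m"))
    zs <- unlist(lapply(t$parts, `[[`, "z"))
    expect_setequal(ms, c("A", "B")); expect_false(anyDuplicated(ms) > 0)
    expect_setequal(zs, c("C", "D")); expect_false(anyDuplicated(zs) > 0)
    expect_gte(length(t$parts), 2)
  }
})

test_that("normalization counts severed mechanism-purview pairs", {
  th <- enumerate_partitions(c("A", "B"), c("C", "D"))
  sigs <- vapply(th, theta_signature, "")
  expect_equal(normalization_factor(th[[match(":CD|AB:", sigs)]]), 4)
  expect_equal(normalization_factor(th[[match("A:C|B:D", sigs)]]), 2)
  expect_equal(normalization_factor(enumerate_partitions("A", "C")[[1]]), 1)
})

test_that("partitioned repertoires noise the severed connections", {
  U <- cnot_AB()
  s10 <- parse_state("10", c("A", "B"))
  m <- mechanism(s10)
  th <- enumerate_partitions(c("A", "B"), c("A", "B"))
  sigs <- vapply(th, theta_signature, "")
  # total cut: all-noise input to a unitary is maximally mixed
  pr <- partitioned_repertoire(U, m, c("A", "B"), th[[match(":AB|AB:", sigs)]],
                               "effect")
  expect_mat_equal(pr$matrix, diag(4) / 4)
  # severing the XOR input: the copy output stays fixed, the XOR output
  # is noised to uniform
  pr2 <- partitioned_repertoire(U, m, c("A", "B"),
                                th[[match("A:AB|B:", sigs)]], "effect")
  expect_mat_equal(pr2$matrix, diag(c(0, 0, 0.5, 0.5)))
  # Bell-creating input: the one-to-one partition destroys entanglement
  mb <- mechanism(parse_state("+0", c("A", "B")))
  pr3 <- partitioned_repertoire(U, mb, c("A", "B"),
                                th[[match("A:A|B:B", sigs)]], "effect")
  expect_mat_equal(pr3$matrix, diag(4) / 4)
})

test_that("phi at a fixed partition matches hand computation", {
  U <- cnot_AB()
  # first-order control mechanism, total cut
  m1 <- mechanism(parse_state("10", c("A", "B")), "A")
  sc <- phi_given_partition(U, m1, "A", enumerate_partitions("A", "A")[[1]],
                            "effect")
  expect_equal(sc$phi, 1, tolerance = 1e-9)
  # Bell mechanism at the one-to-one partition: 2 ibits
  mb <- mechanism(parse_state("+0", c("A", "B")))
  th <- enumerate_partitions(c("A", "B"), c("A", "B"))
  sigs <- vapply(th, theta_signature, "")
  scb <- phi_given_partition(U, mb, c("A", "B"), th[[match("A:A|B:B", sigs)]],
                             "effect")
  expect_equal(scb$phi, 2, tolerance = 1e-9)
  expect_equal(scb$normalized_phi, 1, tolerance = 1e-9)
  # a partition that changes nothing gives zero
  m0 <- mechanism(parse_state("0+", c("A", "B")))
  sc0 <- phi_given_partition(U, m0, c("A", "B"), th[[match("A:A|B:B", sigs)]],
                             "effect")
  expect_equal(sc0$phi, 0, tolerance = 1e-9)
})

test_that("MIP search minimizes normalized phi and reports unnormalized phi", {
  U <- cnot_AB()
  # Bell creation: every partition fully noises the repertoire, so the MIP
  # is a maximally normalized cut and phi stays 2
  mb <- mechanism(parse_state("+0", c("A", "B")))
  mip <- find_mip(U, mb, c("A", "B"), "effect")
  expect_equal(mip$phi, 2, tolerance = 1e-9)
  expect_equal(mip$normalization, 4)
  expect_equal(mip$normalized_phi, 0.5, tolerance = 1e-9)
  # classical input: phi = 1 via a three-part cut with normalization 3
  m10 <- mechanism(parse_state("10", c("A", "B")))
  mip2 <- find_mip(U, m10, c("A", "B"), "effect")
  expect_equal(mip2$phi, 1, tolerance = 1e-9)
  expect_equal(mip2$normalized_phi, 1 / 3, tolerance = 1e-9)
  # fully reducible second-order mechanism
  m0p <- mechanism(parse_state("0+", c("A", "B")))
  expect_equal(find_mip(U, m0p, c("A", "B"), "effect")$phi, 0, tolerance = 1e-9)
})

test_that("non-interacting channels are fully reducible along the factor cut", {
  set.seed(37)
  for (i in 1:3) {
    U <- qchannel(kronecker(random_haar_unitary(2), random_haar_unitary(2)),
                  c("A", "B"))
    st <- compose(list(qstate(random_density_matrix(2), "A", validate = FALSE),
                       qstate(random_density_matrix(2), "B", validate = FALSE)))
    m <- mechanism(st)
    th <- enumerate_partitions(c("A", "B"), c("A", "B"))
    sigs <- vapply(th, theta_signature, "")
    sc <- phi_given_partition(U, m, c("A", "B"), th[[match("A:A|B:B", sigs)]],
                              "effect")
    expect_equal(sc$phi, 0, tolerance = 1e-8)
    expect_equal(find_mip(U, m, c("A", "B"), "effect")$phi, 0, tolerance = 1e-8)
  }
})

test_that("phi never exceeds the intrinsic information on random instances", {
  set.seed(41)
  for (i in 1:8) {
    sc <- random_instance(1000 + i, 2,
                          kind = sample(c("haar_unitary", "permutation",
                                          "random_mixed"), 1))
    for (mu in list("A", c("A", "B"))) {
      m <- mechanism(sc$state, mu)
      ii <- intrinsic_information(sc$channel, m, c("A", "B"), "effect")$value
      mip <- find_mip(sc$channel, m, c("A", "B"), "effect")
      expect_gte(mip$phi, 0)
      expect_lte(mip$phi, ii + 1e-8)
    }
  }
})
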