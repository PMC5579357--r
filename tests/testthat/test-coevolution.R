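test_that("profile correlation equals the phi coefficient of the 2x2 table", {
  expect_equal(as.numeric(profile_pearson(c(1, 1, 0, 0), c(1, 1, 0, 0))), 1)
  expect_equal(as.numeric(profile_pearson(c(1, 1, 0, 0), c(0, 0, 1, 1))), -1)
  expect_equal(as.numeric(profile_pearson(c(1, 1, 0, 0), c(1, 0, 1, 0))),
               phi_from_table(c(1, 1, 0, 0), c(1, 0, 1, 0)))
  expect_error(profile_pearson(c(1, 0), c(1, 0, 1)), "mismatch")
  expect_error(profile_pearson(1, 1), "length")

  # property: phi oracle and stats::cor agree with the implementation
  set.seed(11)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    x <- rbinom(n, 1, runif(1, 0.2, 0.8))
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    r <- as.numeric(profile_pearson(x, y))
    expect_lt(abs(r - phi_from_table(x, y)), 1e-12)
    expect_lt(abs(r - stats::cor(x, y)), 1e-12)
  }
})

test_that("constant profiles yield r = 0 with a flag instead of NaN", {
  r <- profile_pearson(c(1, 1, 1, 1), c(1, 0, 1, 0))
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "constant"))

  cat4 <- toy_catalog4()
  profs <- list(toy_profile("ubiq", c(1, 1, 1, 1)),
                toy_profile("x", c(1, 0, 1, 0)),
                toy_profile("y", c(1, 1, 0, 0)))
  cm <- correlation_matrix(profs)
  expect_true(cm$constant["ubiq"])
  expect_equal(unname(cm$r["ubiq", ]), c(0, 0, 0))
  expect_equal(unname(diag(cm$r)), c(0, 1, 1))
})

test_that("correlation matrix is the symmetric all-pairs map of profile_pearson", {
  set.seed(7)
  catalog <- species_catalog(replicate(12, paste0(
    sample(LETTERS, 1), paste(sample(letters, 3, TRUE), collapse = ""))))
  profs <- random_profiles(6, catalog)
  cm <- correlation_matrix(profs)
  expect_true(isSymmetric(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 6))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(cm$r[i, j],
                 as.numeric(profile_pearson(profs[[i]], profs[[j]])))
  }
})

test_that("joint profiles are the elementwise union with summed copies", {
  a <- toy_profile("a", c(1, 0, 1, 0))
  b <- toy_profile("b", c(0, 1, 1, 0))
  j <- joint_profile(list(a, b), "a+b")
  expect_equal(unname(j$presence), c(1, 1, 1, 0))
  expect_equal(unname(j$copy_number), c(1, 1, 2, 0))
  # idempotence of the union
  jj <- joint_profile(list(a, a), "a+a")
  expect_equal(jj$presence, a$presence)
  expect_error(joint_profile(list(), "none"), "empty")
})

test_that("a multifunctional gene correlates at least as well with the joint
           profile as with either partner when it equals their union", {
  set.seed(21)
  catalog <- species_catalog(replicate(30, paste0(
    sample(LETTERS, 1), paste(sample(letters, 3, TRUE), collapse = ""))))
  for (i in 1:50) {
    ab <- random_profiles(2, catalog)
    enz_bits <- as.integer(ab[[1]]$presence | ab[[2]]$presence)
    if (length(unique(enz_bits)) < 2) next
    enzyme <- phylo_profile("enzyme", enz_bits, catalog)
    jnt <- joint_profile(ab, "joint")
    r_joint <- as.numeric(profile_pearson(enzyme, jnt))
    r_each <- vapply(ab, function(p)
      as.numeric(profile_pearson(enzyme, p)), numeric(1))
    expect_equal(r_joint, 1)
    expect_true(all(r_joint >= r_each - 1e-12))
  }
})

test_that("threshold calibration matches the exhaustive sweep oracle", {
  cm <- worked_cm4()
  ref <- rbind(c("A", "B"), c("C", "D"))
  cal2 <- calibrate_threshold(cm, ref, fold = 2)
  expect_equal(cal2$threshold, 0.5)
  expect_equal(cal2$base_rate, 1 / 3)
  cal6 <- calibrate_threshold(cm, ref, fold = 6)
  expect_equal(cal6$threshold, -1)

  # oracle agreement on the same pair table
  pair_r <- c(0.9, 0.8, 0.5, 0.3, 0.2, 0.1)
  is_ref <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  expect_equal(cal2$threshold, sweep_oracle(pair_r, is_ref, 2))
  expect_equal(cal6$threshold, sweep_oracle(pair_r, is_ref, 6))

  # ref = all pairs -> enrichment identically 1
  all_pairs <- t(utils::combn(c("A", "B", "C", "D"), 2))
  expect_equal(calibrate_threshold(cm, all_pairs, fold = 1)$threshold, 0.1)
  expect_equal(calibrate_threshold(cm, all_pairs, fold = 1.5)$threshold, -1)

  expect_error(calibrate_threshold(cm, ref[0, , drop = FALSE]), "empty")
  expect_error(calibrate_threshold(cm, ref, fold = 0), "positive")
  expect_error(calibrate_threshold(cm, rbind(c("A", "A"))), "self")
})

test_that("calibration threshold is monotone in the requested fold", {
  set.seed(33)
  catalog <- species_catalog(replicate(20, paste0(
    sample(LETTERS, 1), paste(sample(letters, 3, TRUE), collapse = ""))))
  for (rep in 1:20) {
    profs <- random_profiles(6, catalog)
    cm <- correlation_matrix(profs)
    prot <- cm$proteins
    ref <- rbind(prot[1:2], prot[3:4])
    ths <- vapply(c(1, 1.5, 2, 3, 6), function(f)
      calibrate_threshold(cm, ref, fold = f)$threshold, numeric(1))
    real <- ths[ths != -1]
    expect_true(all(diff(real) >= -1e-12))
    # sentinel only ever appears after all attainable folds
    if (any(ths == -1)) expect_true(all(ths[which(ths == -1)[1]:length(ths)] == -1))
  }
})

test_that("average-linkage clustering on d = 1 - r is correct and monotone", {
  # identical profiles merge at height 0
  profs <- list(toy_profile("a", c(1, 0, 1, 0)),
                toy_profile("b", c(1, 0, 1, 0)),
                toy_profile("c", c(1, 1, 0, 0)))
  hc <- cluster_profiles(correlation_matrix(profs))
  expect_equal(hc$height[1], 0)

  # hand-computed three-protein case
  prot <- c("A", "B", "C")
  r <- matrix(c(1, 0.9, 0.1, 0.9, 1, 0.1, 0.1, 0.1, 1), 3,
              dimnames = list(prot, prot))
  cm <- structure(list(proteins = prot, r = r,
                       constant = stats::setNames(rep(FALSE, 3), prot)),
                  class = "coev_cor")
  hc <- cluster_profiles(cm)
  expect_equal(hc$height, c(0.1, 0.9))
  first <- hc$merge[1, ]
  expect_setequal(hc$labels[-first], c("A", "B"))

  # property: merge heights non-decreasing for random profile sets
  set.seed(5)
  catalog <- species_catalog(replicate(15, paste0(
    sample(LETTERS, 1), paste(sample(letters, 3, TRUE), collapse = ""))))
  for (rep in 1:100) {
    cm <- correlation_matrix(random_profiles(sample(3:8, 1), catalog))
    hc <- cluster_profiles(cm)
    expect_true(all(diff(hc$height) >= -1e-12))
    expect_equal(nrow(hc$merge), length(cm$proteins) - 1)
  }
})

test_that("family matching ranks by correlation with deterministic ties", {
  cat4 <- toy_catalog4()
  q <- toy_profile("query", c(1, 1, 0, 0))
  fams <- rbind(FAM1 = c(1, 1, 0, 0),
                FAM2 = c(1, 0, 1, 0),
                FAM3 = c(0, 0, 1, 1),
                FAM4 = c(1, 1, 0, 0))
  colnames(fams) <- cat4$codes
  top <- family_top_matches(q, fams, k = 30)
  expect_equal(nrow(top), 4)  # k beyond the family count returns all
  expect_equal(top$family[1:2], c("FAM1", "FAM4"))  # tie broken by id
  expect_equal(top$r[1], 1)
  expect_error(family_top_matches(q, fams, k = 0), "positive")

  # ranking equals a brute-force sort over profile_pearson
  brute <- sort(apply(fams, 1, function(f)
    as.numeric(profile_pearson(q$presence, f))), decreasing = TRUE)
  expect_equal(top$r, unname(brute))
})

test_that("family profiles propagate subfamily hits to parent families", {
  cat4 <- toy_catalog4()
  asg <- data.frame(seq_id = c("Aaaa000001", "Bbbb000002", "Cccc000003"),
                    family = c("PTHR10000:SF1", "PTHR10000:SF2", "PTHR20000"))
  fp <- family_profiles(asg, cat4)
  expect_true("PTHR10000" %in% rownames(fp))
  expect_equal(unname(fp["PTHR10000", ]), c(1L, 1L, 0L, 0L))
  expect_equal(unname(fp["PTHR10000:SF1", ]), c(1L, 0L, 0L, 0L))
  expect_equal(unname(fp["PTHR20000", ]), c(0L, 0L, 1L, 0L))
})

test_that("recurrent families are tallied across top lists", {
  toplists <- list(
    q1 = c("F1", "F2"), q2 = c("F1", "F3"), q3 = c("F1"), q4 = c("F2"),
    q5 = c("F1", "F2"), q6 = c("F1"), q7 = "F4", q8 = "F5", q9 = "F6",
    q10 = "F7")
  out <- recurrent_families(toplists, min_count = 3)
  expect_equal(out$family, c("F1", "F2"))
  expect_equal(out$count, c(5L, 3L))
  expect_equal(nrow(recurrent_families(toplists, min_count = 11)), 0)
  expect_error(recurrent_families(toplists, min_count = 0), ">= 1")
  # counts equal a brute-force membership tally
  expect_equal(out$count[out$family == "F1"],
               sum(vapply(toplists, function(l) "F1" %in% l, logical(1))))
})
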