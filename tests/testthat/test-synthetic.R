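test_that("simulated species trees are rooted, binary, code-labelled and seeded", {
  t1 <- simulate_species_tree(4, 1)
  expect_true(ape::is.rooted(t1))
  expect_equal(length(t1$tip.label), 4)
  expect_equal(t1$Nnode, 3)  # rooted binary: n - 1 internal nodes
  expect_true(all(grepl("^[A-Za-z]{4}$", t1$tip.label)))
  expect_false(anyDuplicated(t1$tip.label) > 0)

  # determinism: same seed, byte-identical newick
  expect_identical(ape::write.tree(simulate_species_tree(12, 9)),
                   ape::write.tree(simulate_species_tree(12, 9)))

  # different seeds produce different topologies most of the time
  base <- ape::write.tree(simulate_species_tree(10, 1))
  diff_count <- sum(vapply(2:51, function(s)
    !identical(ape::write.tree(simulate_species_tree(10, s)), base),
    logical(1)))
  expect_gt(diff_count, 40)

  expect_error(simulate_species_tree(3, 1), ">= 4")
})

test_that("gene histories follow the single-origin per-branch loss model", {
  tree <- simulate_species_tree(8, 2)
  cfg0 <- simulation_config(n_species = 8, seed = 2, loss_prob = 0,
                            origin_policy = "root")
  g <- simulate_gene_history(tree, cfg0, gene_seed = 5)
  expect_equal(unname(g$profile$presence), rep(1L, 8))
  expect_length(g$loss_branches, 0)
  expect_equal(g$resamples, 0)

  # origin at a fixed internal node with zero loss: presence = its clade
  internal <- length(tree$tip.label) + 2L
  cfg_fix <- simulation_config(n_species = 8, seed = 2, loss_prob = 0,
                               origin_policy = internal)
  g2 <- simulate_gene_history(tree, cfg_fix, gene_seed = 5)
  expect_equal(unname(g2$profile$presence),
               unname(replay_presence(tree, internal)))

  # replay identity for stochastic histories
  cfg <- simulation_config(n_species = 8, seed = 2, loss_prob = 0.3)
  for (s in 1:30) {
    gs <- simulate_gene_history(tree, cfg, gene_seed = s)
    expect_equal(replay_presence(tree, gs$origin, gs$loss_branches),
                 gs$profile$presence)
  }

  # certain extinction errors out after bounded resampling
  cfg1 <- simulation_config(n_species = 8, seed = 2, loss_prob = 1)
  expect_error(simulate_gene_history(tree, cfg1, 1, max_resample = 5),
               "extinct")
  # ... unless extinct genes are explicitly retained
  gx <- simulate_gene_history(tree, cfg1, 1, resample_extinct = FALSE)
  expect_equal(sum(gx$profile$presence), 0)
  expect_error(dollo_reconstruct(gx$profile, tree), "all-absent")
})

test_that("inferred losses never exceed simulated losses (parsimony bound)", {
  tree <- simulate_species_tree(10, 3)
  cfg <- simulation_config(n_species = 10, seed = 3, loss_prob = 0.2)
  for (s in 1:100) {
    g <- simulate_gene_history(tree, cfg, gene_seed = s)
    d <- dollo_reconstruct(g$profile, tree)
    expect_lte(d$loss_count, length(g$loss_branches))
    # and the brute-force optimum can never beat the reconstruction
    bf <- brute_force_min_losses(g$profile, tree)
    expect_equal(bf$loss_count, d$loss_count)
  }
})

test_that("coupled pairs interpolate between identical and independent", {
  tree <- simulate_species_tree(20, 4)
  cfg_ident <- simulation_config(n_species = 20, seed = 4, loss_prob = 0.2,
                                 coupling = 1)
  pair <- simulate_coupled_pair(tree, cfg_ident, pair_seed = 11)
  expect_equal(pair[[1]]$profile$presence, pair[[2]]$profile$presence)
  expect_equal(pair[[1]]$origin, pair[[2]]$origin)

  # coupling separates the mean correlation of pairs
  cfg_hi <- simulation_config(n_species = 20, seed = 4, loss_prob = 0.2,
                              coupling = 0.9)
  cfg_lo <- simulation_config(n_species = 20, seed = 4, loss_prob = 0.2,
                              coupling = 0)
  mean_r <- function(cfg, seeds) {
    mean(vapply(seeds, function(s) {
      pr <- simulate_coupled_pair(tree, cfg, pair_seed = s)
      as.numeric(profile_pearson(pr[[1]]$profile, pr[[2]]$profile))
    }, numeric(1)))
  }
  seeds <- 1:60
  expect_gt(mean_r(cfg_hi, seeds), mean_r(cfg_lo, seeds) + 0.2)
  # independent pairs scatter around zero correlation
  expect_lt(abs(mean_r(cfg_lo, seeds)), 0.2)
})

test_that("multifunctional triplets obey the retention rule", {
  tree <- simulate_species_tree(15, 6)
  cfg <- simulation_config(n_species = 15, seed = 6, loss_prob = 0.25,
                           coupling = 0.3, motif_noise = 0)
  for (s in 1:40) {
    tri <- simulate_multifunctional_triplet(tree, cfg, seed = s)
    pa <- tri$partnerA$profile$presence
    pb <- tri$partnerB$profile$presence
    expect_equal(tri$enzyme$presence,
                 stats::setNames(as.integer(pa | pb), names(pa)))
    jnt <- joint_profile(list(tri$partnerA$profile, tri$partnerB$profile), "j")
    r_joint <- profile_pearson(tri$enzyme, jnt)
    if (!attr(r_joint, "constant")) {
      expect_equal(as.numeric(r_joint), 1)
      for (p in list(tri$partnerA$profile, tri$partnerB$profile))
        expect_gte(as.numeric(r_joint),
                   as.numeric(profile_pearson(tri$enzyme, p)))
    }
  }

  # noise attenuates the enzyme/joint correlation
  cfg_noise <- simulation_config(n_species = 15, seed = 6, loss_prob = 0.25,
                                 coupling = 0.3, motif_noise = 0.5)
  rs <- vapply(1:40, function(s) {
    tri <- simulate_multifunctional_triplet(tree, cfg_noise, seed = s)
    jnt <- joint_profile(list(tri$partnerA$profile, tri$partnerB$profile), "j")
    as.numeric(profile_pearson(tri$enzyme, jnt))
  }, numeric(1))
  expect_lt(mean(rs), 0.6)
})

test_that("emitted fixtures round-trip through the profile builder", {
  tree <- simulate_species_tree(12, 7)
  catalog <- catalog_from_tree(tree)
  cfg <- simulation_config(n_species = 12, seed = 7, loss_prob = 0.2,
                           coupling = 0.9, motif_noise = 0)
  genes <- lapply(1:5, function(s)
    simulate_gene_history(tree, cfg, gene_seed = s, name = paste0("g", s)))
  names(genes) <- paste0("g", 1:5)
  outdir <- tempfile("fix")
  em <- emit_fixture_dataset(genes, tree, cfg, outdir,
                             motif_partners = c(g1 = "g2"))

  profs <- build_profiles_dir(outdir, catalog)
  for (nm in names(genes))
    expect_equal(profs[[nm]]$presence, genes[[nm]]$profile$presence)

  # the truth table replays to the same profiles
  truth <- read.table(em$truth, sep = "\t", header = TRUE,
                      colClasses = "character")
  expect_equal(truth$profile,
               vapply(genes, function(g)
                 paste(g$profile$presence, collapse = ""), character(1),
                 USE.NAMES = FALSE))

  # the emitted tree reparses against the catalog
  expect_silent(read_species_tree(em$tree, catalog))

  # motif scan of the carrier's sequences reproduces carrier AND partner
  can <- motif_pattern("canonical_MIM")
  og <- read_orthogroup_fasta(file.path(outdir, "g1.fasta"))
  anchor <- og$ids[which(em$motif_truth$g1[parse_species_code(og$ids)] == 1)[1]]
  mp <- scan_alignment_window(og$sequences, can, anchor, catalog, slack = 5)
  expect_equal(mp$presence, em$motif_truth$g1)
  expect_equal(unname(em$motif_truth$g1),
               as.integer(genes$g1$profile$presence &
                            genes$g2$profile$presence))

  # byte-identical re-emission under the same config and seed
  outdir2 <- tempfile("fix2")
  emit_fixture_dataset(genes, tree, cfg, outdir2, motif_partners = c(g1 = "g2"))
  for (f in list.files(outdir, pattern = "fasta$")) {
    expect_identical(readLines(file.path(outdir, f)),
                     readLines(file.path(outdir2, f)))
  }
})
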