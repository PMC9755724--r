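test_that("simulation is byte-identical for identical config and seed", {
  cfg <- make_preset("vertebrate_4a", seed = 77)
  f1 <- simulate_family(cfg)
  f2 <- simulate_family(cfg)
  expect_identical(f1$records, f2$records)
  expect_identical(f1$exon_maps, f2$exon_maps)
  expect_identical(f1$truth$carriers, f2$truth$carriers)
  p1 <- tempfile(); p2 <- tempfile()
  on.exit(unlink(c(p1, p2)))
  write_fasta(f1$records, p1); write_fasta(f2$records, p2)
  expect_identical(readLines(p1), readLines(p2))
  f3 <- simulate_family(make_preset("vertebrate_4a", seed = 78))
  expect_false(identical(f1$records$residues, f3$records$residues))
})

test_that("zero rates and no events conserve the root exactly", {
  cfg <- sim_config(tree = "((a:1,b:1)ab:1,(c:1,d:1)cd:1)r;",
                    architecture = data.frame(region = "whole", length = 300L,
                                              rate = 0),
                    seed = 79)
  fam <- simulate_family(cfg)
  expect_equal(length(unique(fam$records$residues)), 1)
})

test_that("per-region identities order by configured rate in every replicate", {
  for (s in 1:5) {
    m <- run_recovery_experiment("recovery_3rate", seed = s)
    ri <- unlist(m$region_identity)
    expect_true(ri[["9-13"]] > ri[["1-4"]])   # rate 0.01 vs 0.05
    expect_true(ri[["1-4"]] > ri[["4a"]])     # rate 0.05 vs 0.30
    expect_equal(m$rate_identity_spearman, 1)
  }
})

test_that("generator identity follows the closed-form decay", {
  # leaves at branch length t=1 each side; expected pairwise site identity
  # is 1/20 + (19/20) exp(-2 r t) under uniform-redraw substitution
  cfg <- sim_config(tree = "(L1:1,L2:1)root;",
                    architecture = data.frame(
                      region = c("slow", "mid", "fast"),
                      length = c(3000L, 3000L, 3000L),
                      rate = c(0.01, 0.05, 0.30)),
                    seed = 83)
  fam <- simulate_family(cfg)
  s1 <- strsplit(fam$records$residues[1], "")[[1]]
  s2 <- strsplit(fam$records$residues[2], "")[[1]]
  map <- fam$exon_maps[fam$exon_maps$record_id == "L1", ]
  for (i in seq_len(nrow(map))) {
    idx <- (map$start[i] + 1):map$end[i]
    obs <- mean(s1[idx] == s2[idx])
    r <- c(0.01, 0.05, 0.30)[i]
    expct <- 1 / 20 + (19 / 20) * exp(-2 * r)
    se <- sqrt(expct * (1 - expct) / length(idx))
    expect_lt(abs(obs - expct) / se, 3)
  }
})

test_that("exonization marks exactly the descendants of the named branch", {
  fam <- simulate_family(make_preset("recovery_3rate", seed = 89))
  expect_equal(sort(fam$truth$carriers[["4a"]]), c("A", "B", "C", "D"))
  ins <- fam$truth$inserts
  expect_equal(sort(unique(ins$record_id)), c("A", "B", "C", "D"))
  expect_true(all(ins$end - ins$start >= 230))
  # the insert sits between the two anchor regions in every carrier map
  for (id in c("A", "B")) {
    mp <- fam$exon_maps[fam$exon_maps$record_id == id, ]
    expect_equal(mp$exon_label, c("1-4", "4a", "5-8", "9-13"))
  }
})

test_that("independently exonized inserts share no homology", {
  sc <- load_scoring_scheme()
  fam <- simulate_family(make_preset("vertebrate_4a", seed = 97))
  m <- suppressMessages(identity_matrix(fam$records, fam$exon_maps,
                                        region_spec("exon4a", "4a"),
                                        sc))
  off <- m[upper.tri(m)]
  expect_true(all(off < 30))   # cross-lineage inserts at the noise floor
})

test_that("indels stay within regions and keep maps consistent", {
  cfg <- sim_config(tree = "((a:1,b:1)ab:1,c:2)r;",
                    architecture = data.frame(
                      region = c("x", "y"), length = c(150L, 250L),
                      rate = c(0.05, 0.05)),
                    indel_rate = 0.01, indel_length_p = 0.4, seed = 101)
  fam <- simulate_family(cfg)
  expect_silent(validate_exon_map(fam$exon_maps))
  lens <- tapply(fam$exon_maps$end, fam$exon_maps$record_id, max)
  expect_equal(as.integer(lens[fam$records$record_id]),
               nchar(fam$records$residues))
  # indels actually happened somewhere at this rate
  n_ind <- sum(vapply(fam$truth$branch_log,
                      function(b) length(b$indels), 0L))
  expect_gt(n_ind, 0)
})

test_that("configs validate their tree, branches and regions", {
  arch <- data.frame(region = "x", length = 100L, rate = 0.1)
  expect_error(make_preset("martian"), "unknown preset")
  expect_error(sim_config("(a:1,b:1)r;", arch,
                          exonization_events = list(list(
                            branch = "nope", insert_length_mean = 100,
                            insert_after_region = "x"))),
               "unknown branch")
  expect_error(sim_config("(a:1,b:1)r;", arch,
                          exonization_events = list(list(
                            branch = "a", insert_length_mean = 100,
                            insert_after_region = "zz"))),
               "unknown region")
})

test_that("YAML configs reproduce the in-code configuration", {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  writeLines(c(
    "tree: '((a:1,b:1)ab:0.5,c:1.5)r;'",
    "architecture:",
    "  - {region: '1-4', length: 170, rate: 0.05}",
    "  - {region: '5-8', length: 100, rate: 0.01}",
    "indel_rate: 0.001",
    "seed: 7",
    "exonization_events:",
    "  - {branch: ab, insert_length_mean: 251, insert_length_sd: 5,",
    "     insert_after_region: '1-4', label: 4a, rate: 0.3}"), f)
  cfg <- read_sim_config(f)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$seed, 7L)
  expect_equal(cfg$architecture$length, c(170L, 100L))
  fam <- simulate_family(cfg)
  expect_equal(sort(fam$truth$carriers[["4a"]]), c("a", "b"))
})
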