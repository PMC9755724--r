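sc <- load_scoring_scheme()

test_that("zero-rate families give 100% identity in every table row", {
  cfg <- sim_config(tree = "((a:1,b:1)ab:1,c:2)r;",
                    architecture = data.frame(region = c("1-4", "5-8", "9-13"),
                                              length = c(60L, 40L, 80L),
                                              rate = 0),
                    seed = 5)
  fam <- simulate_family(cfg)
  regions <- list(n = region_spec("n", "1-4"), m = region_spec("m", "5-8"),
                  c = region_spec("c", "9-13"), full = region_spec("full"))
  tab <- region_homology_table(fam$records[1, ], fam$exon_maps,
                               fam$records[-1, ], fam$exon_maps, regions, sc)
  expect_equal(nrow(tab), 8)
  expect_true(all(tab$identity_pct == 100))
})

test_that("region identities match hand-computed substitution counts", {
  set.seed(53)
  lens <- c(80L, 60L, 100L)
  ks <- c(4L, 9L, 0L)
  base <- vapply(lens, random_aa, "")
  mut <- mapply(mutate_k, base, ks)
  rec <- protein_records(c("ref", "tgt"),
                         c(paste(base, collapse = ""), paste(mut, collapse = "")))
  ends <- cumsum(lens)
  map <- do.call(rbind, lapply(c("ref", "tgt"), function(id)
    data.frame(record_id = id, exon_label = c("e1", "e2", "e3"),
               start = ends - lens, end = ends)))
  regions <- lapply(setNames(c("e1", "e2", "e3"), c("e1", "e2", "e3")),
                    function(l) region_spec(l, l))
  tab <- region_homology_table(rec[1, ], map, rec[2, ], map, regions, sc)
  expect_equal(tab$identity_pct, 100 * (lens - ks) / lens)
  expect_equal(tab$ref_region_len, lens)
})

test_that("identity matrices are symmetric with a 100 diagonal", {
  rec <- protein_records(c("x", "y"), rep(random_aa(40), 2))
  m <- identity_matrix(rec, region = region_spec("full"), scheme = sc)
  expect_equal(unname(m), matrix(100, 2, 2))
  fam <- simulate_family(make_preset("recovery_3rate", seed = 59))
  mm <- suppressMessages(identity_matrix(fam$records, fam$exon_maps,
                                         region_spec("full"), sc))
  expect_equal(unname(diag(mm)), rep(100, nrow(mm)))
  expect_true(all(mm == t(mm)))
  # identity decreases with tree distance: siblings beat cross-clade pairs
  expect_gt(mm["A", "B"], mm["A", "E"])
  expect_gt(mm["C", "D"], mm["C", "F"])
})

test_that("significance needs both overall and contiguous-window identity", {
  expect_equal(classify_homology(list(identity_pct = 100,
                                      max_window_identity = 100))$status,
               "significant")
  # scattered: 15% identity spread evenly, no conserved window
  set.seed(61)
  base <- random_aa(240)
  scattered <- mutate_k(base, 204)
  st <- alignment_stats(pairwise_alignment(base, scattered), sc)
  expect_lt(st$identity_pct, 20)
  cl <- classify_homology(st)
  expect_equal(cl$status, "nonsignificant")
  expect_match(cl$reason, "<")
  # ~25% overall identity concentrated in one identical 30-residue block
  blk <- random_aa(30)
  blockA <- paste0(random_aa(35), blk, random_aa(55))
  blockB <- paste0(random_aa(35), blk, random_aa(55))
  aln <- pairwise_alignment(blockA, blockB)
  st2 <- alignment_stats(aln, sc)
  expect_gt(st2$identity_pct, 20)
  expect_lt(st2$identity_pct, 45)
  expect_equal(st2$max_window_identity, 100)
  cl2 <- classify_homology(st2)
  expect_equal(cl2$status, "significant")
})

test_that("significance is monotone in both statistics", {
  for (id in c(10, 20, 30, 60)) {
    for (w in c(20, 40, 80)) {
      a <- classify_homology(list(identity_pct = id, max_window_identity = w))
      b <- classify_homology(list(identity_pct = id + 5,
                                  max_window_identity = w + 5))
      expect_false(a$status == "significant" && b$status == "nonsignificant")
    }
  }
})

test_that("conservation ratio does plain normalized-mean arithmetic", {
  expect_equal(conservation_ratio(c(50, 60), c(50, 60))$value, 100)
  expect_equal(conservation_ratio(10, 40)$rounded, 25)
  r1 <- conservation_ratio(c(24, 18), c(91, 53))
  r2 <- conservation_ratio(c(24, 18) * 3.7, c(91, 53) * 3.7)
  expect_equal(r1$value, r2$value)  # scale invariance
  expect_error(conservation_ratio(numeric(0), 1), "nonempty")
  expect_error(conservation_ratio(1, 0), "zero denominator")
})

test_that("similarity ranking puts true carriers of a segment on top", {
  set.seed(67)
  segment <- random_aa(80)
  carriers <- c("c1", "c2", "c3")
  res <- sapply(1:6, function(i) {
    body <- random_aa(200)
    if (i <= 3) paste0(substr(body, 1, 90), segment, substr(body, 91, 200))
    else body
  })
  db <- protein_records(c(carriers, "n1", "n2", "n3"), res)
  hits <- rank_by_similarity(segment, db, sc)
  expect_equal(sort(hits$record_id[1:3]), carriers)
  # identity is diluted by the free end gaps around the embedded segment,
  # but carriers still dominate non-carriers on both statistics
  expect_gt(min(hits$identity_pct[1:3]), max(hits$identity_pct[4:6]))
  expect_true(max(hits$score[4:6]) < min(hits$score[1:3]))
  # exact member query ranks itself first with identity 100
  hits2 <- rank_by_similarity(db$residues[4], db, sc)
  expect_equal(hits2$record_id[1], "n1")
  expect_equal(hits2$identity_pct[1], 100)
  # matched interval localizes the segment within the carrier
  h1 <- hits[hits$record_id == "c1", ]
  expect_lte(abs(h1$start - 90), 3)
  expect_lte(abs(h1$end - 170), 3)
})
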