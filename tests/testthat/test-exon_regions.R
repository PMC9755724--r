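sc <- load_scoring_scheme()

test_that("regions are extracted by label in map order", {
  set.seed(31)
  res <- random_aa(400)
  rec <- protein_records("r1", res)
  map <- data.frame(record_id = "r1", exon_label = c("4", "4a", "5"),
                    start = c(0L, 100L, 351L), end = c(100L, 351L, 400L))
  r <- extract_region(rec, map, region_spec("exon4a", "4a"))
  expect_equal(r$length, 251)
  expect_equal(r$sequence, substring(res, 101, 351))
  both <- extract_region(rec, map, region_spec("flank", c("4", "5")))
  expect_equal(both$sequence,
               paste0(substring(res, 1, 100), substring(res, 352, 400)))
  full <- extract_region(rec, map, region_spec("full"))
  expect_equal(full$length, 400)
  expect_error(extract_region(rec, map, region_spec("x", "4a-L")), "4a-L")
})

test_that("length bands classify every observed big-exon size correctly", {
  expect_equal(classify_exon4a(c(100, 251, 355)), c("none", "4a", "4a-L"))
  tbl <- mapt_reference_homology()
  s4a <- tbl$size_aa[tbl$region == "exon4a" & !is.na(tbl$size_aa)]
  s4al <- tbl$size_aa[tbl$region == "exon4aL" & !is.na(tbl$size_aa)]
  expect_equal(range(s4a), c(208, 320))
  expect_equal(range(s4al), c(347, 400))
  expect_true(all(classify_exon4a(s4a) == "4a"))
  expect_true(all(classify_exon4a(s4al) == "4a-L"))
  expect_error(classify_exon4a(-1), "negative")
})

test_that("self-inference returns the annotated interval exactly", {
  fam <- simulate_family(make_preset("recovery_3rate", seed = 41))
  ref <- get_record(fam$records, "A")
  truth <- fam$exon_maps[fam$exon_maps$record_id == "A" &
                           fam$exon_maps$exon_label == "4a", ]
  call <- infer_big_exon(ref, ref, fam$exon_maps, sc,
                         anchors = c("1-4", "5-8"))
  expect_equal(call$start, truth$start)
  expect_equal(call$end, truth$end)
  expect_equal(call$class_label, "4a")
  expect_equal(call$anchor_confidence, 1)
})

test_that("an inserted big exon is recovered against an insert-free reference", {
  # no indels: boundaries must land within a few residues of truth even
  # when the reference lacks the insert entirely (251-column gap)
  fam <- simulate_family(make_preset("recovery_3rate", seed = 43))
  ref <- get_record(fam$records, "E")  # non-carrier
  for (id in c("A", "B", "C", "D")) {
    tru <- fam$truth$inserts[fam$truth$inserts$record_id == id, ]
    call <- infer_big_exon(get_record(fam$records, id), ref, fam$exon_maps,
                           sc, anchors = c("1-4", "5-8"))
    expect_true(call$class_label == "4a")
    expect_lte(abs(call$start - tru$start), 3)
    expect_lte(abs(call$end - tru$end), 3)
  }
  # non-carrier against non-carrier: nothing between the anchors
  call <- infer_big_exon(get_record(fam$records, "F"), ref, fam$exon_maps,
                         sc, anchors = c("1-4", "5-8"))
  expect_equal(call$class_label, "none")
  expect_lt(call$length, 150)
})

test_that("a 4a-L-sized insert classifies as 4a-L", {
  fam <- simulate_family(make_preset("vertebrate_4a", seed = 47))
  ref <- get_record(fam$records, "human")
  call <- infer_big_exon(get_record(fam$records, "fish"), ref, fam$exon_maps,
                         sc, anchors = c("1-4", "5-8"))
  expect_equal(call$class_label, "4a-L")
  tru <- fam$truth$inserts[fam$truth$inserts$record_id == "fish", ]
  expect_gt(call$length, 335)
  # deep divergence wobbles the boundaries; the call must still cover the
  # bulk of the true insert and nothing much beyond it
  overlap <- max(0, min(call$end, tru$end) - max(call$start, tru$start))
  expect_gt(overlap / (tru$end - tru$start), 0.8)
  expect_gt(overlap / call$length, 0.8)
})

test_that("missing anchor exons raise an informative error", {
  rec <- protein_records("r1", random_aa(100))
  map <- data.frame(record_id = "r1", exon_label = "4",
                    start = 0L, end = 100L)
  expect_error(infer_big_exon(rec, rec, map, sc), "anchor exon")
})
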