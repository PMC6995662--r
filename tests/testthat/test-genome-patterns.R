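test_that("mountain profiles report per-group medians in genome order", {
  co <- small_cohort()
  st <- co$samples
  groups <- list(current = st$sample_id[st$smoking == "current"],
                 never = st$sample_id[st$smoking == "never"])
  prof <- mountain_profile(co$cnv, co$annotation, groups)
  # genome order: chromosome rank then position
  ord <- order(tobsig:::chrom_order(prof$chromosome), prof$position)
  expect_identical(ord, seq_len(nrow(prof)))
  # autosomal background sits at the diploid baseline
  aut <- !(prof$chromosome %in% c("chrX", "chrY"))
  amp <- unlist(lapply(co$truth$amplicon_regions, `[[`, "genes"))
  bg <- aut & !(prof$symbol %in% amp)
  expect_lt(max(abs(prof$median_never[bg] - 2)), 0.35)
  # sample order within a group is irrelevant
  prof2 <- mountain_profile(co$cnv, co$annotation,
                            lapply(groups, rev))
  expect_identical(prof, prof2)
  # a single-sample group is that sample's values
  one <- mountain_profile(co$cnv, co$annotation,
                          list(solo = st$sample_id[1]))
  expect_equal(one$median_solo,
               unname(co$cnv$values[one$symbol, st$sample_id[1]]))
  expect_error(mountain_profile(co$cnv, co$annotation, list(x = "nope")),
               "no samples")
})

test_that("acrocentric chromosomes carry q-arm genes only", {
  co <- small_cohort()
  acro <- co$annotation[co$annotation$chromosome %in%
                          c("chr13", "chr14", "chr15", "chr21", "chr22"), ]
  expect_true(all(acro$arm == "q"))
})

test_that("deflection table matches the Welch oracle and flips with labels", {
  prep <- small_prepared()
  defl <- deflection_table(prep$layers$cnv, prep$labels)
  v <- prep$layers$cnv$values
  i <- match(c("SG0005", "SG0100"), defl$table$symbol)
  oracle <- apply(v[defl$table$symbol[i], ], 1, function(r)
    t.test(r[prep$labels == 1], r[prep$labels == 0])$p.value)
  expect_equal(defl$table$p_value[i], unname(oracle), tolerance = 1e-10)
  # planted amplicon genes exceed the Bonferroni line
  amp <- unlist(lapply(small_cohort()$truth$amplicon_regions, `[[`, "genes"))
  expect_gte(mean(defl$table$exceeds[defl$table$symbol %in% amp]), 0.9)
  # direction is antisymmetric in the labels
  defl_sw <- deflection_table(prep$layers$cnv, 1L - prep$labels)
  strong <- defl$table$p_value < 1e-4
  expect_true(all(defl$table$direction[strong] != defl_sw$table$direction[strong]))
})

test_that("null cohorts put essentially nothing above the Bonferroni line", {
  fracs <- vapply(1:5, function(s) {
    co <- generate_cohort(null_cohort_config(s + 40))
    prep <- tobsig:::prepare_cohort(co)
    deflection_table(prep$layers$cnv, prep$labels)$fraction_exceeding
  }, numeric(1))
  expect_lte(median(fracs), 0.001)
})

test_that("focal peak calling reports the planted amplicon plateau exactly", {
  co <- small_cohort()
  st <- co$samples
  prof <- mountain_profile(co$cnv, co$annotation,
                           list(current = st$sample_id[st$smoking == "current"]))
  peaks <- focal_peaks(prof, "current", min_prominence = 0.5, window = 15)
  full <- Filter(function(a) length(a$genes) == 7, co$truth$amplicon_regions)
  for (am in full) {
    hit <- peaks[peaks$chromosome == am$chromosome & peaks$start >= am$start - 1 &
                   peaks$end <= am$end + 1, ]
    expect_identical(nrow(hit), 1L)
    expect_identical(sort(strsplit(hit$genes, ",")[[1]]), sort(am$genes))
  }
  # monotone profile has no peaks
  flat <- data.frame(symbol = paste0("G", 1:30), chromosome = "chr1",
                     arm = "q", position = seq(1e6, 3e7, length.out = 30),
                     median_x = seq(2, 3, length.out = 30))
  expect_identical(nrow(focal_peaks(flat, "x", min_prominence = 0.5,
                                    window = 9, tie_tol = 0.001)), 0L)
  # two equal peaks are both reported; calling is translation invariant
  two <- flat
  two$median_x <- 2
  two$median_x[c(10, 20)] <- 3.5
  pk <- focal_peaks(two, "x", min_prominence = 0.5, window = 7, tie_tol = 0.01)
  expect_identical(nrow(pk), 2L)
  two_shift <- two
  two_shift$position <- two_shift$position + 5e7
  pk2 <- focal_peaks(two_shift, "x", min_prominence = 0.5, window = 7,
                     tie_tol = 0.01)
  expect_identical(pk$genes, pk2$genes)
})

test_that("chrY medians expose the male never-smoker deficit", {
  co <- study_cohort(1)
  st <- co$samples
  male <- st$gender == "male"
  prof <- mountain_profile(co$cnv, co$annotation, list(
    male_never = st$sample_id[male & st$smoking == "never"],
    male_current = st$sample_id[male & st$smoking == "current"]))
  med <- chromosome_medians(prof, "chrY")
  expect_lt(abs(med["male_current"] - 1), 0.1)
  expect_lt(abs(med["male_never"] - 0.6), 0.1)
})
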