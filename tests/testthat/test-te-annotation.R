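test_that("family assignment follows the 80% covered-query rule", {
  hits <- data.frame(
    te_id = c("t1", "t1", "t2", "t2"),
    subject = c("famX", "famY", "famX", "famY"),
    qstart = c(0, 900, 0, 500), qend = c(900, 1000, 500, 1000),
    evalue = 1e-10)
  a <- assign_families(hits)
  expect_equal(unname(a["t1"]), "famX")   # 90% of covered query
  expect_true(is.na(a["t2"]))             # 50/50 split: unassigned

  # high e-value rows are ignored
  hits2 <- data.frame(te_id = "t3", subject = "famZ",
                      qstart = 0, qend = 500, evalue = 1e-3)
  expect_true(is.na(assign_families(hits2)["t3"]))
})

test_that("iterated assignment recruits TEs through earlier-round assignments", {
  # t_a hits a reference family directly; t_b only hits t_a
  hits <- data.frame(
    te_id = c("t_a", "t_b"),
    subject = c("famQ", "t_a"),
    qstart = c(0, 0), qend = c(1000, 800), evalue = 1e-20)
  one_round <- assign_families(hits, rounds = 1)
  expect_true(is.na(one_round["t_b"]))
  full <- assign_families(hits, rounds = 4)
  expect_equal(unname(full["t_a"]), "famQ")
  expect_equal(unname(full["t_b"]), "famQ")
})

test_that("merging applies the 500-bp same-family / different-family rules", {
  tes <- data.frame(
    chrom = "chr1",
    start = c(1000, 2300, 10000, 11300, 20000, 20600 + 600),
    end   = c(2000, 3300, 11000, 12300, 20600, 21800),
    id = paste0("te", 1:6),
    family = c("A", "A", "A", "B", "A", "A"),
    stringsAsFactors = FALSE)
  out <- merge_te_records(tes)
  # te1+te2 merged (gap 300, same family); te3/te4 removed (gap 300,
  # different families); te5/te6 kept apart (gap 600)
  expect_equal(nrow(out), 3)
  expect_equal(out$start[1], 1000); expect_equal(out$end[1], 3300)
  expect_false(any(out$id %in% c("te3", "te4")))
  expect_true(all(c("te5", "te6") %in% out$id))

  # excluded families are dropped after merging
  tel <- data.frame(chrom = "chr1", start = c(1, 5000), end = c(600, 5600),
                    id = c("x", "y"), family = c("HeT-A", "DINE-1"),
                    stringsAsFactors = FALSE)
  expect_equal(nrow(merge_te_records(tel)), 0)

  # unassigned families are neither merged nor removed
  nas <- data.frame(chrom = "chr1", start = c(1000, 1600),
                    end = c(1500, 2200), id = c("u1", "u2"),
                    family = NA_character_, stringsAsFactors = FALSE)
  expect_equal(nrow(merge_te_records(nas)), 2)
})

test_that("merging never grows the set and agrees with an interval oracle", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 80
    start <- sort(sample.int(3e5, n))
    tes <- data.frame(chrom = "chr1", start = start,
                      end = start + sample(500:2000, n, replace = TRUE),
                      id = paste0("te", seq_len(n)), family = "A",
                      stringsAsFactors = FALSE)
    tes <- tes[order(tes$start), ]
    tes <- tes[c(TRUE, tes$start[-1] >= cummax(tes$end[-n])), ]  # non-nested
    out <- merge_te_records(tes)
    expect_lte(nrow(out), nrow(tes))
    # single-family instance: result must equal gap<=500 interval reduction
    ir <- IRanges::reduce(IRanges::IRanges(tes$start + 1, tes$end),
                          min.gapwidth = 501)
    expect_equal(out$start, IRanges::start(ir) - 1)
    expect_equal(out$end, IRanges::end(ir))
    # merged spans contain their inputs
    for (i in seq_len(nrow(tes)))
      expect_true(any(out$start <= tes$start[i] & out$end >= tes$end[i]))
  }
})

test_that("length/euchromatin filtering is correct and idempotent", {
  eu <- data.frame(chrom = "chr1", start = 1000, end = 50000)
  tes <- data.frame(chrom = "chr1",
                    start = c(2000, 3000, 500, 49800),
                    end = c(2450, 3500, 1200, 50600),
                    id = paste0("te", 1:4), stringsAsFactors = FALSE)
  out <- filter_te_records(tes, euchromatin = eu)
  expect_equal(out$id, "te2")  # 450 bp too short; te3/te4 cross the boundary
  expect_identical(filter_te_records(out, euchromatin = eu), out)
  expect_error(filter_te_records(tes, euchromatin = NULL), "boundary")
})

test_that("full-length classification uses the 70% canonical-length rule", {
  expect_equal(classify_te_length(c(750, 700, 699, 500, 900),
                                  c(1000, 1000, 1000, 1000, NA)),
               c("full", "full", "truncated", "truncated", "unknown"))
})

test_that("location categories follow exon > intron > intergenic precedence", {
  genes <- data.frame(chrom = "chr1", start = 1000, end = 9000, id = "g1")
  exons <- data.frame(chrom = "chr1", start = c(1000, 8000),
                      end = c(2000, 9000), id = "g1")
  tes <- data.frame(chrom = "chr1", start = c(1500, 4000, 20000),
                    end = c(1900, 4600, 20600))
  expect_equal(te_location_category(tes, genes, exons),
               c("exonic", "intronic", "intergenic"))
})
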