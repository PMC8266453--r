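test_that("hypergeometric upper tail matches exact enumeration", {
  # P(X >= 4) drawing 4 from 10 with 5 successes = C(5,4)C(5,0)/C(10,4)
  expect_equal(hypergeom_upper_tail(4, 5, 4, 10), 5 / 210)
  expect_equal(hypergeom_upper_tail(4, 5, 4, 10),
               oracle_hyper(4, 5, 4, 10))
  # P(X >= 0) = 1; all-success background gives 1 for any feasible k
  expect_equal(hypergeom_upper_tail(0, 5, 4, 10), 1.0)
  expect_equal(hypergeom_upper_tail(3, 8, 3, 8), 1.0)
  expect_error(hypergeom_upper_tail(5, 4, 6, 10), "invalid")
  expect_error(hypergeom_upper_tail(1, 11, 2, 10), "invalid")
})

test_that("BH adjustment equals the literal step-up formula", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  set.seed(31)
  for (i in 1:5) {
    p <- runif(sample(3:20, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
    # order invariance (up to the same reordering)
    ix <- sample(length(p))
    expect_equal(bh_adjust(p[ix]), bh_adjust(p)[ix])
    # monotone in the raw p-values
    ord <- order(p)
    expect_true(!is.unsorted(bh_adjust(p)[ord]))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("GMT round-trips and rejects malformed lines", {
  path <- withr::local_tempfile(fileext = ".gmt")
  col <- data.frame(set_id = c("S1", "S2"),
                    name = c("first set", "second"),
                    stringsAsFactors = FALSE)
  col$members <- list(c("A", "B", "C"), "D")   # one-member set allowed
  write_gmt(col, path)
  back <- read_gmt(path)
  expect_identical(back$set_id, col$set_id)
  expect_identical(back$members, col$members)
  expect_identical(lengths(back$members), c(3L, 1L))
  writeLines(c("S1\tdesc\tA", "S2\tno-members"), path)
  expect_error(read_gmt(path), "line 2")
  writeLines(c("S1\tdesc\tA", "S1\tdesc\tB"), path)
  expect_error(read_gmt(path), "duplicate")
})

test_that("over-representation analysis obeys its row invariants", {
  gs <- gen_gene_sets(n_sets = 20, background_size = 300,
                      query_size = 15, seed = 4)
  rows <- enrich(gs$query, gs$collection, filter_on = "none")
  expect_true(all(rows$hit_count >= 1))
  expect_true(all(rows$hit_count <= pmin(rows$set_size, rows$query_size)))
  expect_true(all(rows$set_size <= rows$background_size))
  expect_true(all(rows$p_adjusted >= rows$p_value - 1e-12))
  expect_true(all(lengths(strsplit(rows$hit_genes, ",")) ==
                    rows$hit_count))
  # sorted by p then set_id
  expect_true(!is.unsorted(rows$p_value))
  # the spiked set attains the smallest adjusted p
  expect_identical(rows$set_id[which.min(rows$p_adjusted)],
                   gs$manifest$ground_truth$spiked_set_id)
})

test_that("a query saturating the background is not called enriched", {
  col <- data.frame(set_id = "S1", name = "everything",
                    stringsAsFactors = FALSE)
  col$members <- list(c("A", "B", "C", "D"))
  rows <- enrich(c("A", "B", "C", "D"), col, filter_on = "none")
  expect_equal(rows$p_value, 1.0)
  expect_identical(nrow(enrich(c("A", "B", "C", "D"), col,
                               filter_on = "raw", alpha = 0.05)), 0L)
  expect_error(enrich("ZZZ", col), "share no symbols")
})

test_that("zero-hit sets stay in the BH family", {
  col <- data.frame(set_id = c("S1", "S2", "S3"),
                    name = c("a", "b", "c"), stringsAsFactors = FALSE)
  col$members <- list(c("A", "B"), c("C", "D"), c("E", "F"))
  rows <- enrich(c("A", "B"), col, filter_on = "none")
  expect_identical(nrow(rows), 1L)     # only the hit set is reported
  # but m = 3 in the correction: adjusted = raw * 3 / 1
  expect_equal(rows$p_adjusted, pmin(1, rows$p_value * 3))
})

test_that("the top-15 pathway fixture reproduces its hit counts", {
  tab <- read.delim(fx("kegg_top15_dd.tsv"), stringsAsFactors = FALSE)
  expect_identical(nrow(tab), 15L)
  col <- data.frame(set_id = tab$set_id, name = tab$name,
                    stringsAsFactors = FALSE)
  col$members <- strsplit(tab$gene_ids, ",", fixed = TRUE)
  overlap <- read_symbol_list(fx("overlap_targets_dd.txt"))
  rows <- enrich(overlap, col, filter_on = "none")
  sero <- rows[rows$set_id == "hsa04726", ]
  expect_identical(sero$hit_count, 4L)
  expect_identical(sero$hit_genes, "APP,CACNA1C,MAOA,MAOB")
  # every fixture row's printed count is reproduced
  expect_identical(rows$hit_count[match(tab$set_id, rows$set_id)],
                   tab$count)
})

test_that("category tallies partition the enriched rows", {
  rows <- data.frame(set_id = c("S1", "S2", "S3"))
  expect_identical(categorize(rows, c(S1 = "X", S2 = "X", S3 = "Y")),
                   c(X = 2L, Y = 1L))
  expect_identical(categorize(rows[0, , drop = FALSE], character(0)),
                   stats::setNames(integer(0), character(0)))
  expect_error(categorize(rows, c(S1 = "X", S2 = "X")), "S3")
  set.seed(9)
  cats <- sample(c("metabolism", "disease", "signaling"), 30, TRUE)
  rows2 <- data.frame(set_id = sprintf("S%02d", 1:30))
  map <- stats::setNames(cats, rows2$set_id)
  got <- categorize(rows2, map)
  expect_identical(sum(got), 30L)
  expect_identical(got[sort(unique(cats))],
                   stats::setNames(as.integer(table(cats)[sort(unique(cats))]),
                                   sort(unique(cats))))
})

test_that("top-N selection is deterministic under p-value ties", {
  rows <- data.frame(set_id = c("B1", "A1", "C1"),
                     p_value = c(0.01, 0.01, 0.02))
  # emulate the enrich() ordering contract on a tie fixture
  ord <- order(rows$p_value, rows$set_id)
  rows <- rows[ord, ]
  expect_identical(top_n_sets(rows, 2)$set_id, c("A1", "B1"))
  expect_identical(nrow(top_n_sets(rows, 10)), 3L)
})
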