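# Operon inference and regulatory-site assignment.

mk_feats <- function(starts, ends, strands, ids = NULL) {
  n <- length(starts)
  gene_features(ids %||% paste0("g", seq_len(n)), "chr", starts, ends,
                strands)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("small gaps merge and a strand flip always splits", {
  # gaps of 10 and 20 bp under max_gap 60 -> one operon
  f <- mk_feats(c(1, 111, 231), c(100, 210, 330), rep("+", 3))
  ops <- infer_operons(f, max_gap = 60)
  expect_equal(nrow(ops), 1)
  expect_equal(ops$n_genes, 3)
  expect_equal(ops$genes, "g1,g2,g3")

  # gaps 10 and 80 -> sizes 2 and 1 (the 70-100 bp "alone" band)
  f2 <- mk_feats(c(1, 111, 291), c(100, 210, 400), rep("+", 3))
  ops2 <- infer_operons(f2, max_gap = 60)
  expect_equal(sort(ops2$n_genes), c(1, 2))

  # tiny gap but opposite strands -> always split
  f3 <- mk_feats(c(1, 106), c(100, 200), c("+", "-"))
  expect_equal(nrow(infer_operons(f3, max_gap = 60)), 2)
})

test_that("operons partition the gene set", {
  set.seed(21)
  gaps <- sample(10:200, 40, replace = TRUE)
  lens <- sample(100:900, 40, replace = TRUE)
  ends <- cumsum(gaps + lens)
  starts <- ends - lens + 1
  f <- mk_feats(starts, ends, sample(c("+", "-"), 40, TRUE))
  ops <- infer_operons(f, max_gap = 60)
  members <- unlist(strsplit(ops$genes, ","))
  expect_setequal(members, f$id)
  expect_equal(anyDuplicated(members), 0)
})

test_that("duplicate ids and bad coordinates are rejected", {
  expect_error(gene_features(c("a", "a"), "chr", c(1, 10), c(5, 20),
                             c("+", "+")), "duplicate")
  expect_error(gene_features("a", "chr", 10, 5, "+"), "start <= end")
})

test_that("sites map to the operon they sit upstream of", {
  # two operons on + strand; one hit 50 bp upstream of the second
  f <- mk_feats(c(1, 501), c(400, 900), c("+", "+"))
  ops <- infer_operons(f, max_gap = 60)
  hits <- data.frame(contig = "chr", start = 435L, strand = "+",
                     matched = strrep("A", 16), stringsAsFactors = FALSE)
  out <- assign_sites_to_operons(hits, ops, f)
  expect_equal(out$operon, ops$operon[ops$start == 501])
  expect_equal(out$distance, 501L - 450L)

  # a hit inside a coding region stays unmapped
  hits2 <- data.frame(contig = "chr", start = 200L, strand = "+",
                      matched = strrep("A", 16), stringsAsFactors = FALSE)
  expect_true(is.na(assign_sites_to_operons(hits2, ops, f)$operon))

  # out of window -> unmapped
  hits3 <- data.frame(contig = "chr", start = 30L, strand = "+",
                      matched = strrep("A", 16), stringsAsFactors = FALSE)
  f_far <- mk_feats(1000, 1400, "+")
  ops_far <- infer_operons(f_far)
  expect_true(is.na(assign_sites_to_operons(hits3, ops_far,
                                            f_far)$operon)) # 954 bp away
})

test_that("equidistant divergent operons resolve by strand then coordinate", {
  # divergent pair: minus-strand operon ends at 400, plus-strand starts 617;
  # a 16-bp hit at 501..516 is 101 bp from both 5' starts
  f <- mk_feats(c(1, 617), c(400, 900), c("-", "+"))
  ops <- infer_operons(f, max_gap = 60)
  hit <- data.frame(contig = "chr", start = 501L, strand = "-",
                    matched = strrep("A", 16), stringsAsFactors = FALSE)
  out <- assign_sites_to_operons(hit, ops, f)
  expect_equal(out$operon, ops$operon[ops$strand == "-"])
  hit$strand <- "+"
  out2 <- assign_sites_to_operons(hit, ops, f)
  expect_equal(out2$operon, ops$operon[ops$strand == "+"])
})
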