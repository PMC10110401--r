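test_that("count tables round-trip through both dialects", {
  mat <- matrix(c(1L, 3L, 2L, 4L), nrow = 2,
                dimnames = list(c("g1", "g2"), c("S1", "S2")))
  cm <- toy_counts(mat)
  for (fmt in c("tsv", "mtx")) {
    path <- file.path(tempdir(), paste0("rt.", fmt))
    sheet <- file.path(tempdir(), "rt_sheet.tsv")
    write_count_table(cm, path, sample_sheet = sheet)
    back <- read_count_table(path, sheet)
    expect_identical(back$counts, cm$counts)
    expect_identical(back$samples, cm$samples)
  }
})

test_that("count matrix columns follow sample-sheet order", {
  mat <- matrix(1:4, nrow = 2, dimnames = list(c("g1", "g2"), c("S2", "S1")))
  path <- file.path(tempdir(), "ord.tsv")
  sheet_path <- file.path(tempdir(), "ord_sheet.tsv")
  tab <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(toy_sheet(2), sheet_path, sep = "\t", quote = FALSE, row.names = FALSE)
  cm <- read_count_table(path, sheet_path)   # sheet says S1, S2
  expect_identical(colnames(cm$counts), c("S1", "S2"))
  expect_identical(cm$counts["g1", "S1"], mat["g1", "S1"])
  expect_identical(cm$counts["g2", "S2"], mat["g2", "S2"])
})

test_that("count loading rejects contract violations by name", {
  mat <- matrix(1:4, nrow = 2, dimnames = list(c("g1", "g2"), c("S1", "S2")))
  path <- file.path(tempdir(), "bad.tsv")
  sheet_path <- file.path(tempdir(), "bad_sheet.tsv")
  write.table(data.frame(gene = rownames(mat), mat, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  sheet3 <- toy_sheet(3)                     # lists S3, absent from the matrix
  write.table(sheet3, sheet_path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_count_table(path, sheet_path), "S3")

  expect_error(count_matrix(matrix(1:4, 2, dimnames = list(c("g1", "g1"), NULL)),
                            toy_sheet(2)), "duplicate gene")
  expect_error(count_matrix(matrix(c(1, -2, 3, 4), 2,
                                   dimnames = list(c("g1", "g2"), NULL)),
                            toy_sheet(2)), "negative")

  # fractional entry in a MatrixMarket triplet
  m <- Matrix::Matrix(matrix(c(1, 2.5, 3, 4), 2), sparse = TRUE)
  mtx <- file.path(tempdir(), "frac.mtx")
  Matrix::writeMM(m, mtx)
  writeLines(c("g1", "g2"), paste0(mtx, ".rownames"))
  writeLines(c("S1", "S2"), paste0(mtx, ".colnames"))
  write.table(toy_sheet(2), sheet_path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_count_table(mtx, sheet_path), "fractional")
})

test_that("FASTA loading normalizes to uppercase RNA and keeps order", {
  fa <- file.path(tempdir(), "seqs.fasta")
  writeLines(c(">g1", "auuua", ">g2 some description", "ATTTA"), fa)
  seqs <- read_sequences(fa)
  expect_identical(seqs, c(g1 = "AUUUA", g2 = "AUUUA"))

  # idempotent under its own normalization
  write_sequences(seqs, fa)
  expect_identical(read_sequences(fa), seqs)

  writeLines(c(">g1", "", ">g2", "AU"), fa)
  expect_error(read_sequences(fa), "g1")
  writeLines(character(0), fa)
  expect_length(read_sequences(fa), 0)
  writeLines(c(">g1", "AUT"), fa)
  expect_error(read_sequences(fa), "mix T and U")
})

test_that("GMT collections de-duplicate members and report bad lines", {
  gmt <- file.path(tempdir(), "sets.gmt")
  writeLines("inflam\tdesc\tg1\tg2\tg2", gmt)
  coll <- read_gene_sets(gmt)
  expect_identical(coll$inflam, c("g1", "g2"))
  expect_identical(attr(coll, "descriptions")[["inflam"]], "desc")

  writeLines(character(0), gmt)
  expect_length(read_gene_sets(gmt), 0)

  writeLines("x\tdesc", gmt)
  expect_error(read_gene_sets(gmt), "line 1")

  # round trip
  writeLines(c("a\td1\tg1\tg2", "b\td2\tg3"), gmt)
  coll <- read_gene_sets(gmt)
  gmt2 <- file.path(tempdir(), "sets2.gmt")
  write_gene_sets(coll, gmt2)
  expect_identical(unclass(read_gene_sets(gmt2))[1:2], unclass(coll)[1:2])
})
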