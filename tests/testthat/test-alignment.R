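test_that("aligned FASTA parses and round-trips", {
  txt <- ">sp1\nACGT-ACGTAC\n>sp2\nACGTTACGTAC\n>sp3\nACGT-ACGTAC\n"
  aln <- read_alignment(txt)
  expect_s3_class(aln, "dna_alignment")
  expect_length(aln$ids, 3)
  expect_equal(aln$ncol, 11)
  expect_true(all(nchar(aln$seqs) == 11))

  one <- read_alignment(">only\nacgtacgt\n")
  expect_length(one$ids, 1)
  expect_equal(unname(one$seqs[1]), "ACGTACGT")
})

test_that("clustal format is recognised", {
  block1 <- strrep("ACGT", 15)
  block2 <- "ACGTACGTAC"
  txt <- paste(c("CLUSTAL 2.1 multiple sequence alignment", "", "",
                 paste0("sp1             ", block1),
                 paste0("sp2             ", block1),
                 paste0("                ", strrep("*", 60)), "",
                 paste0("sp1             ", block2),
                 paste0("sp2             ", block2),
                 paste0("                ", strrep("*", 10))),
               collapse = "\n")
  aln <- read_alignment(txt)
  expect_equal(aln$ncol, 70)
  expect_setequal(aln$ids, c("sp1", "sp2"))
  expect_equal(unname(aln$seqs[["sp1"]]), paste0(block1, block2))
})

test_that("malformed alignments are rejected", {
  expect_error(read_alignment(">a\nACGTACGTAA\n>b\nACGTACGTA\n"),
               class = "swarmprimer_format_error")
  expect_error(read_alignment(">a\nACGXACGT\n"),
               class = "swarmprimer_format_error")
  expect_error(read_alignment("no_such_file.fasta"),
               class = "swarmprimer_input_error")
})

test_that("reference template strips gaps and preserves positions", {
  aln <- read_alignment(">r\nAC-GT\n>q\nACCGT\n")
  tpl <- reference_template(aln, "r", circular = FALSE)
  expect_equal(tpl$seq, "ACGT")
  expect_equal(tpl$length, 4)
  expect_error(reference_template(aln, "missing"),
               class = "swarmprimer_lookup_error")

  # a known subsequence keeps its ungapped coordinates
  aln2 <- read_alignment(">r\nACTTAGCGAATG\n>q\nACTTAGCGAATG\n")
  tpl2 <- reference_template(aln2, "r", circular = FALSE)
  expect_equal(substr(tpl2$seq, 2, 11), "CTTAGCGAAT")
})

test_that("conserved regions match hand-computed cases", {
  # identical records: one region covering everything
  s <- paste(rep("ACGTTGCA", 20), collapse = "")
  aln <- read_alignment(paste0(">a\n", s, "\n>b\n", s, "\n"))
  reg <- conserved_regions(aln, "a", min_len = 18, circular = TRUE)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start, 1)
  expect_equal(reg$end, 160)

  # one mismatch at column 50 of a gap-free 100-column alignment
  a <- strsplit(paste(rep("ACGTTGCAAC", 10), collapse = ""), "")[[1]]
  b <- a; b[50] <- setdiff(c("A", "C", "G", "T"), a[50])[1]
  aln2 <- read_alignment(paste0(">a\n", paste(a, collapse = ""),
                                "\n>b\n", paste(b, collapse = ""), "\n"))
  reg2 <- conserved_regions(aln2, "a", min_len = 18, circular = FALSE)
  expect_equal(reg2$start, c(1, 51))
  expect_equal(reg2$end, c(49, 100))

  # differing every 10th column: no run reaches 18
  b3 <- a
  b3[seq(10, 100, by = 10)] <- vapply(b3[seq(10, 100, by = 10)],
    function(x) setdiff(c("A", "C", "G", "T"), x)[1], character(1))
  aln3 <- read_alignment(paste0(">a\n", paste(a, collapse = ""),
                                "\n>b\n", paste(b3, collapse = ""), "\n"))
  expect_equal(nrow(conserved_regions(aln3, "a", min_len = 18)), 0)
})

test_that("N and gap columns are non-conserved; wrap merge needs circular", {
  aln <- read_alignment(">a\nAANAAAAAAA\n>b\nAANAAAAAAA\n")
  reg <- conserved_regions(aln, "a", min_len = 2, circular = FALSE)
  expect_equal(reg$start, c(1, 4))
  expect_equal(reg$end, c(2, 10))

  # circular: the two runs flanking the break merge across the origin
  regc <- conserved_regions(aln, "a", min_len = 2, circular = TRUE)
  expect_equal(nrow(regc), 1)
  expect_true(regc$wraps)
  expect_equal(regc$start, 4)
  expect_equal(regc$end, 2)
  expect_equal(regc$length, 9)
})

test_that("conserved regions agree with a naive column scan", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      L <- sample(200:600, 1)
      anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      mk <- function() {
        x <- anc
        hit <- which(runif(L) < 0.03)
        x[hit] <- vapply(x[hit], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
        paste(x, collapse = "")
      }
      seqs <- c(a = mk(), b = mk(), c = mk())
      aln <- read_alignment(paste0(">a\n", seqs[1], "\n>b\n", seqs[2],
                                   "\n>c\n", seqs[3], "\n"))
      got <- conserved_regions(aln, "a", min_len = 10, circular = TRUE)
      want <- naive_conserved_regions(seqs, "a", min_len = 10, circular = TRUE)
      expect_equal(as.data.frame(got), want, ignore_attr = TRUE)
      # regions are pairwise disjoint on the reference
      if (nrow(got) > 1) {
        flat <- unlist(lapply(seq_len(nrow(got)), function(i) {
          if (got$wraps[i]) c(got$start[i]:L, 1:got$end[i])
          else got$start[i]:got$end[i]
        }))
        expect_equal(anyDuplicated(flat), 0)
      }
    }
  })
})

test_that("BED writer emits 0-based half-open intervals", {
  aln <- read_alignment(">a\nAANAAAAAAA\n>b\nAANAAAAAAA\n")
  tpl <- reference_template(aln, "a")
  reg <- conserved_regions(aln, "a", min_len = 2, circular = FALSE)
  path <- withr::local_tempfile(fileext = ".bed")
  write_regions_bed(reg, path, tpl)
  bed <- read.table(path, sep = "\t")
  expect_equal(bed$V2, c(0, 3))
  expect_equal(bed$V3, c(2, 10))
})
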