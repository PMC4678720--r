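test_that("FASTA reading normalizes case and U and validates records", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGT"), f)
  asm <- read_genome_fasta(f, "orgA")
  expect_identical(unname(asm$chromosomes["chr1"]), "ACGT")

  writeLines(c(">c1 some description", "acgu"), f)
  asm <- read_genome_fasta(f, "orgA")
  expect_identical(unname(asm$chromosomes["c1"]), "ACGT")

  writeLines(c(">a", "ACGT", ">a", "GGGG"), f)
  expect_error(read_genome_fasta(f, "orgA"), "duplicate chromosome")

  writeLines(c(">bad", "ACXT"), f)
  expect_error(read_genome_fasta(f, "orgA"), "non-IUPAC")

  writeLines(character(0), f)
  expect_error(read_genome_fasta(f, "orgA"), "empty|parse")

  writeLines(c(">amb", "ACRYT"), f)  # ambiguity codes collapse to N
  expect_identical(unname(read_genome_fasta(f, "orgA")$chromosomes["amb"]),
                   "ACNNT")
})

test_that("annotation reading handles TSV rows, GFF3 CDS spans, bad strands", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchromosome\tstrand\tcds_start\tcds_end",
               "g1\tchr1\t+\t101\t400"), f)
  g <- read_annotation(f, "tsv", organism_id = "orgA")
  expect_identical(g$gene_id, "g1")
  expect_identical(g$strand, "+")
  expect_identical(g$cds_start, 101L)
  expect_identical(g$cds_end, 400L)

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tCDS\t101\t200\t.\t+\t0\tID=cds1;Parent=gA",
               "chr1\tsrc\tCDS\t301\t400\t.\t+\t0\tID=cds2;Parent=gA",
               "chr1\tsrc\tCDS\t500\t700\t.\t-\t0\tID=cds3;Parent=gB"), gff)
  g <- read_annotation(gff, "gff3", organism_id = "orgA")
  g <- g[order(g$gene_id), ]
  expect_identical(g$cds_start, c(101L, 500L))
  expect_identical(g$cds_end, c(400L, 700L))  # multi-exon span rule

  writeLines(c("gene_id\tchromosome\tstrand\tcds_start\tcds_end",
               "g1\tchr1\t.\t101\t400"), f)
  expect_error(read_annotation(f, "tsv", organism_id = "orgA"),
               "unknown strand")

  # coordinates outside the chromosome are rejected when bounds are known
  writeLines(c("gene_id\tchromosome\tstrand\tcds_start\tcds_end",
               "g1\tchr1\t+\t95\t400"), f)
  asm <- make_assembly(c(chr1 = random_dna(200)))
  expect_error(read_annotation(f, "tsv", organism_id = "orgA", assembly = asm),
               "outside chromosome")
})

test_that("upstream window extraction is strand-aware and skips short flanks", {
  set.seed(41)
  chr <- random_dna(120)
  asm <- make_assembly(c(chr1 = chr))
  g <- make_genes("g1", "chr1", "+", 61, 120)
  w <- extract_upstream_windows(asm, g)
  expect_identical(w$sequence, substr(chr, 1, 60))
  expect_identical(w$kind, "utr60")

  asm2 <- make_assembly(c(chr1 = strrep("A", 100)))
  g2 <- make_genes("g2", "chr1", "-", 10, 40)
  w2 <- extract_upstream_windows(asm2, g2)
  expect_identical(w2$sequence, strrep("T", 60))

  g3 <- make_genes("g3", "chr1", "+", 30, 110)
  w3 <- extract_upstream_windows(asm, g3)
  expect_identical(nrow(w3), 0L)
  expect_identical(attr(w3, "skipped")$reason, "insufficient_flank")
})

test_that("upstream extraction is symmetric under genome reverse complement", {
  set.seed(7)
  for (rep in 1:20) {
    L <- sample(150:400, 1)
    chr <- random_dna(L)
    s <- sample(61:(L - 20), 1)
    e <- min(L, s + sample(6:30, 1))
    gplus <- make_genes("gp", "chr", "+", s, e)
    # mirrored gene on the reverse-complemented chromosome
    gminus <- make_genes("gp", "chr", "-", L - e + 1, L - s + 1)
    wp <- extract_upstream_windows(make_assembly(c(chr = chr)), gplus)
    wm <- extract_upstream_windows(make_assembly(c(chr = rc_chr(chr))), gminus)
    expect_identical(wp$sequence, wm$sequence)
  }
})

test_that("every emitted window has length 60 and emitted + skipped = total", {
  set.seed(11)
  chr <- random_dna(2000)
  asm <- make_assembly(c(chr1 = chr))
  g <- make_genes(paste0("g", 1:30), "chr1", sample(c("+", "-"), 30, TRUE),
                  cds_start = sample(1:1800, 30), cds_end = 0)
  g$cds_end <- pmin(2000L, g$cds_start + sample(20:200, 30, TRUE))
  for (fun in list(extract_upstream_windows, extract_negative_control_windows)) {
    w <- fun(asm, g)
    expect_true(all(nchar(w$sequence) == 60L))
    expect_identical(nrow(w) + nrow(attr(w, "skipped")), nrow(g))
  }
})

test_that("negative-control windows sit immediately 5' of the stop codon", {
  set.seed(13)
  chr <- random_dna(200)
  asm <- make_assembly(c(chr1 = chr))
  g <- make_genes("g1", "chr1", "+", 1, 120)
  w <- extract_negative_control_windows(asm, g)
  expect_identical(w$sequence, substr(chr, 58, 117))
  expect_identical(w$kind, "negctrl60")

  gshort <- make_genes("g2", "chr1", "+", 1, 30)
  ws <- extract_negative_control_windows(asm, gshort)
  expect_identical(nrow(ws), 0L)
  expect_identical(attr(ws, "skipped")$reason, "cds_too_short")

  # strand mirror: the minus-strand image of g1 yields the same sense window
  gm <- make_genes("g1", "chr1", "-", 200 - 120 + 1, 200)
  wm <- extract_negative_control_windows(make_assembly(c(chr1 = rc_chr(chr))), gm)
  expect_identical(wm$sequence, w$sequence)
})

test_that("intergenic regions run to the nearest upstream CDS boundary", {
  chr <- random_dna(1000)
  asm <- make_assembly(c(chr1 = chr))
  g <- make_genes(c("gA", "gB"), "chr1", "+", c(101, 501), c(400, 900))
  ig <- compute_intergenic_regions(asm, g)
  expect_identical(ig$length[ig$gene_id == "gB"], 100L)
  expect_identical(ig$sequence[ig$gene_id == "gB"], substr(chr, 401, 500))

  gfirst <- make_genes("g1", "chr1", "+", 51, 300)
  expect_identical(compute_intergenic_regions(asm, gfirst)$length, 50L)

  gabut <- make_genes(c("gA", "gB"), "chr1", "+", c(101, 501), c(500, 900))
  ig <- compute_intergenic_regions(asm, gabut)
  expect_identical(ig$length[ig$gene_id == "gB"], 0L)
  expect_identical(ig$sequence[ig$gene_id == "gB"], "")
})

test_that("ortholog tables build consistent forward and reverse maps", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("og_id\tgene_id", "OG1\tg1", "OG1\tg2", "OG2\tg3"), f)
  ot <- read_ortholog_groups(f)
  expect_setequal(ot$groups$OG1, c("g1", "g2"))
  expect_identical(ot$groups$OG2, "g3")
  expect_identical(og_of(ot, c("g2", "gX")), c("OG1", NA))
  # reverse index consistent with forward map
  for (g in names(ot$forward)) {
    expect_true(g %in% ot$groups[[ot$forward[[g]]]])
  }

  writeLines(c("og_id\tgene_id", "OG1\tg1", "OG2\tg1"), f)
  expect_error(read_ortholog_groups(f), "more than one")

  writeLines("og_id\tgene_id", f)
  expect_warning(ot0 <- read_ortholog_groups(f), "empty")
  expect_length(ot0$forward, 0)
})
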