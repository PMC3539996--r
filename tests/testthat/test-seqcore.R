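# double-stranded DNA model, site scanning, digestion

test_that("revcomp handles palindromes, rejects bad input, and is an involution", {
  expect_identical(revcomp("GAATTC"), "GAATTC")
  expect_identical(revcomp("CATATG"), "CATATG")
  expect_identical(revcomp("ACGT"), "ACGT")
  expect_identical(revcomp("AAC"), "GTT")
  expect_error(revcomp(""), "non-empty")
  expect_error(revcomp("ACGN"), "position 4")
  set.seed(7)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(1:40, 1), TRUE), collapse = "")
    expect_identical(revcomp(revcomp(s)), s)
    expect_identical(revcomp(s),
                     as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))))
  }
})

test_that("molecule invariants are enforced", {
  expect_error(dna("", "linear"), "non-empty")
  expect_error(dna("ACGTN", "circular"), "invalid character")
  expect_error(dna("ACGT", "circular",
                   left_end = sticky_end("five_prime", "CTAG")),
               "carry no ends")
  expect_error(dna("ACGTACGT", "linear", features("x", "orf", 4, 12)),
               "beyond the end")
  # circular wrap-around is permitted
  m <- dna("ACGTACGT", "circular", features("x", "orf", 6, 10))
  expect_equal(nrow(m$features), 1L)
  expect_error(dna("ACGT", "linear", features(c("a", "a"), "orf", c(0, 2), c(2, 4))),
               "duplicate feature label")
})

test_that("canonical rotation matches a naive all-rotations minimum", {
  set.seed(11)
  for (i in 1:40) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(2:30, 1), TRUE), collapse = "")
    expect_identical(canonical_rotation(s), naive_canonical(s))
  }
  expect_true(same_plasmid("ACGGT", "CGGTA"))          # rotation
  expect_true(same_plasmid("AACGT", revcomp("AACGT"))) # strand flip
})

test_that("the shipped enzyme registry derives the expected overhangs", {
  reg <- enzymes()
  expect_setequal(names(reg),
                  c("XbaI", "SpeI", "NheI", "AvrII", "NdeI", "EcoRI",
                    "BamHI", "BglII", "SphI", "PstI", "KpnI"))
  ov <- function(n) enzyme_overhang(enz(n))
  for (nm in c("XbaI", "SpeI", "NheI", "AvrII"))
    expect_equal(ov(nm), list(kind = "five_prime", overhang = "CTAG"))
  expect_equal(ov("NdeI"), list(kind = "five_prime", overhang = "TA"))
  expect_equal(ov("EcoRI"), list(kind = "five_prime", overhang = "AATT"))
  expect_equal(ov("BamHI"), list(kind = "five_prime", overhang = "GATC"))
  expect_equal(ov("BglII"), list(kind = "five_prime", overhang = "GATC"))
  expect_equal(ov("SphI"), list(kind = "three_prime", overhang = "CATG"))
  expect_equal(ov("PstI"), list(kind = "three_prime", overhang = "TGCA"))
  expect_equal(ov("KpnI"), list(kind = "three_prime", overhang = "GTAC"))
  # every shipped recognition sequence is palindromic
  for (e in reg) expect_identical(revcomp(e$recognition), e$recognition)
})

test_that("scan_sites finds hand-scanned positions, including across the origin", {
  m <- dna("GGCTAGCAATTTCCTAGGAT", "circular")
  expect_identical(scan_sites(m, "NheI"), 1L)
  expect_identical(scan_sites(m, "AvrII"), 12L)
  expect_identical(scan_sites(m, "EcoRI"), integer())
  # origin-spanning site: GAAT|TC wraps
  w <- dna("TCGGGGGAAT", "circular")
  expect_identical(scan_sites(w, "EcoRI"), 6L)
  # the same sequence linear has no site
  expect_identical(scan_sites(dna("TCGGGGGAAT", "linear"), "EcoRI"), integer())
})

test_that("scan counts are strand-invariant for the palindromic set", {
  set.seed(13)
  for (i in 1:30) {
    m <- random_molecule_with_sites(sample(40:120, 1), sample(0:3, 1))
    rc <- revcomp_molecule(m)
    for (nm in names(enzymes()))
      expect_identical(length(scan_sites(m, nm)), length(scan_sites(rc, nm)))
  }
})

test_that("digestion of the 20-mer worked example gives two CTAG-ended fragments", {
  m <- dna("GGCTAGCAATTTCCTAGGAT", "circular")
  fr <- digest(m, c("NheI", "AvrII"))
  expect_length(fr, 2L)
  lens <- sort(vapply(fr, function(f) nchar(f$seq), integer(1L)))
  expect_identical(lens, c(9L, 11L))
  expect_identical(sum(lens), 20L)
  for (f in fr) {
    expect_identical(f$left_end$kind, "five_prime")
    expect_identical(f$left_end$overhang, "CTAG")
    expect_identical(f$right_end$kind, "five_prime")
    expect_identical(f$right_end$overhang, "CTAG")
  }
})

test_that("single-cut linearisation preserves length; uncut is a signal not an error", {
  m <- dna(paste0("CCTAGG", strrep("AT", 20)), "circular", id = "mini")
  fr <- digest(m, "AvrII")
  expect_length(fr, 1L)
  expect_identical(nchar(fr[[1L]]$seq), nchar(m$seq))
  un <- digest(m, "EcoRI")
  expect_true(is_uncut(un))
  expect_length(un, 0L)
})

test_that("cut sites closer than the overhang collide", {
  # TCTAGATCT carries XbaI at 0 and BglII at 3; their 4 nt overhang arcs
  # ([1,5) and [4,8)) overlap, so complete digestion is ill-defined
  m <- dna(paste0("TCTAGATCT", strrep("T", 30)), "circular")
  expect_error(digest(m, c("XbaI", "BglII")), "site-collision")
})

test_that("k cuts give k fragments (circular) or k+1 (linear), lengths conserved", {
  set.seed(17)
  tried <- 0L
  for (i in 1:200) {
    L <- sample(40:200, 1)
    m <- random_molecule_with_sites(L, sample(0:4, 1))
    k <- 0L
    for (nm in names(enzymes())) k <- k + length(scan_sites(m, nm))
    fr <- tryCatch(digest(m, as.list(names(enzymes()))), error = function(e) NULL)
    if (is.null(fr)) next # rare chance site collision
    tried <- tried + 1L
    if (is_uncut(fr)) {
      expect_identical(k, 0L)
      next
    }
    expect_length(fr, k)
    lens <- vapply(fr, function(f) nchar(f$seq), integer(1L))
    expect_identical(sum(lens), L)
    # agree with the rotate-and-cut brute-force oracle
    expect_identical(sort(lens),
                     oracle_circular_fragment_lengths(m$seq, names(enzymes())))
    # linear version of the same sequence: k' cuts -> k'+1 fragments
    lin <- dna(m$seq, "linear")
    klin <- 0L
    for (nm in names(enzymes())) klin <- klin + length(scan_sites(lin, nm))
    frl <- tryCatch(digest(lin, as.list(names(enzymes()))), error = function(e) NULL)
    if (!is.null(frl)) {
      expect_length(frl, klin + 1L)
      expect_identical(sum(vapply(frl, function(f) nchar(f$seq), integer(1L))), L)
    }
  }
  expect_gt(tried, 150L)
})

test_that("features are sliced and re-anchored through digestion", {
  #        0123456789...
  seq <- paste0("AAAA", "GAATTC", "CCCC", "CATATG", "TTTT")
  m <- dna(seq, "linear",
           features(c("left", "mid"), c("promoter", "orf"), c(0, 11), c(4, 15)))
  fr <- digest(m, c("EcoRI", "NdeI"))
  expect_length(fr, 3L)
  expect_identical(fr[[1L]]$features$label, "left")
  expect_identical(fr[[1L]]$features$start, 0L)
  mid <- fr[[2L]]$features
  expect_identical(mid$label, "mid")
  # fragment 2 starts at the EcoRI top cut (position 5)
  expect_identical(mid$start, 11L - 5L)
  expect_identical(mid$end, 15L - 5L)
})

test_that("flipping a molecule twice restores it", {
  m <- dna("GGCTAGCAATTTCCTAGGAT", "circular")
  for (f in digest(m, c("NheI", "AvrII"))) {
    ff <- revcomp_molecule(revcomp_molecule(f))
    expect_identical(ff$seq, f$seq)
    expect_identical(ff$left_end$overhang, f$left_end$overhang)
    expect_identical(ff$right_end$kind, f$right_end$kind)
  }
  # asymmetric overhangs (TA vs AATT): top-strand length changes on flip
  v <- dna(paste0("CATATG", "GGGG", "GAATTC"), "linear")
  fr <- digest(v, c("NdeI", "EcoRI"))
  midflip <- revcomp_molecule(fr[[2L]])
  expect_identical(revcomp_molecule(midflip)$seq, fr[[2L]]$seq)
})
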