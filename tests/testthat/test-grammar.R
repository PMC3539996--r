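# slot grammar, part/plasmid validation, metadata

test_that("the slot table defines eight chained roles", {
  st <- slot_table()
  expect_identical(nrow(st), 8L)
  expect_setequal(st$role, c("host_ori", "ecoli_ori", "marker", "regulator",
                             "promoter", "rbs", "orf", "terminator"))
  # cassette chain: promoter-NheI-rbs-NdeI-orf
  get <- function(r) st[st$role == r, ]
  expect_identical(get("promoter")$right, get("rbs")$left)
  expect_identical(get("rbs")$right, get("orf")$left)
  # backbone chain: regulator-BglII-ecoli_ori-SphI-marker-PstI-host_ori
  expect_identical(get("regulator")$right, get("ecoli_ori")$left)
  expect_identical(get("ecoli_ori")$right, get("marker")$left)
  expect_identical(get("marker")$right, get("host_ori")$left)
  expect_identical(get("promoter")$left, "XbaI")
  expect_identical(get("terminator")$right, "SpeI")
})

test_that("validate_part flags planted cassette sites and ORF defects", {
  bad <- part("bad", "orf", paste0("ATGAAA", "GAATTC", "AAATAA"))
  rep <- validate_part(bad)
  expect_false(report_ok(rep))
  hit <- rep[rep$code == "internal_site", ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$position, 6L)
  expect_identical(hit$severity, "error")
  # frame / stop checks
  expect_true(any(validate_part(part("x", "orf", "TTGAAATAA"))$code == "orf_start"))
  expect_true(any(validate_part(part("x", "orf", "ATGAAAA"))$code == "orf_frame"))
  expect_true(any(validate_part(part("x", "orf", "ATGAAACCC"))$code == "orf_stop"))
  expect_true(any(validate_part(part("x", "orf", "ATGTAAAAATAA"))$code == "orf_internal_stop"))
  expect_error(part("x", "widget", "ACGT"), "unknown part role")
})

test_that("designed fixture ORFs validate cleanly; RBS spacing mismatches warn", {
  reg <- test_registry()
  for (id in c("eGFP", "mCherry"))
    expect_identical(nrow(validate_part(registry_get(reg, id, "orf"))), 0L)
  # the fixture sod RBS measures spacing 7; declaring 9 must raise a warning
  sod <- registry_get(reg, "sod", "rbs")
  expect_identical(nrow(validate_part(sod)), 0L)
  lied <- part("sod2", "rbs", sod$core_seq, meta = list(native_spacing = 9L))
  rep <- validate_part(lied)
  expect_true(any(rep$code == "rbs_spacing" & rep$severity == "warning"))
})

test_that("flank_part applies the slot contract, NdeI embedding the ATG", {
  reg <- test_registry()
  p <- registry_get(reg, "tac", "promoter")
  expect_identical(flank_part(p), paste0("TCTAGA", p$core_seq, "GCTAGC"))
  tm <- registry_get(reg, "rrnBT1T2", "terminator")
  expect_identical(flank_part(tm), paste0("CCTAGG", tm$core_seq, "ACTAGT"))
  orf <- registry_get(reg, "eGFP", "orf")
  fl <- flank_part(orf)
  expect_identical(substr(fl, 1, 6), "CATATG")
  expect_identical(substr(fl, nchar(fl) - 5, nchar(fl)), "GAATTC")
  expect_identical(length(ptgr:::.scan_seq(fl, "CATATG")), 1L)
  expect_identical(length(ptgr:::.scan_seq(fl, "GAATTC")), 1L)
  # round trip for every role
  for (p in reg$parts)
    expect_identical(excise_core(flank_part(p), p$role), p$core_seq)
})

test_that("single-TU assembly yields a clean plasmid for every fixture combination", {
  reg <- test_registry()
  combos <- expand.grid(prom = c("tac", "cspB", "sod"),
                        rbs = c("sod", "lacZ", "cspB"),
                        orf = c("eGFP", "mCherry"),
                        ori = c("pGA1", "pCRY4", "pNG2"),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    m <- assemble_single_tu(
      host_ori = registry_get(reg, cb$ori, "host_ori"),
      ecoli_ori = registry_get(reg, "ColE1", "ecoli_ori"),
      marker = registry_get(reg, "kan", "marker"),
      regulator = if (cb$prom == "tac") registry_get(reg, "lacI", "regulator"),
      promoter = registry_get(reg, cb$prom, "promoter"),
      rbs = registry_get(reg, cb$rbs, "rbs"),
      orf = registry_get(reg, cb$orf, "orf"),
      terminator = registry_get(reg, "rrnBT1T2", "terminator"))
    rep <- validate_plasmid(m)
    expect_identical(nrow(rep), 0L)
    expect_true(all(ptgr:::.site_census(m) == 1L))
  }
})

test_that("degenerate single-TU forms keep their empty slot flanks", {
  reg <- test_registry()
  base <- function(...) assemble_single_tu(
    host_ori = registry_get(reg, "pGA1", "host_ori"),
    ecoli_ori = registry_get(reg, "ColE1", "ecoli_ori"),
    marker = registry_get(reg, "kan", "marker"),
    terminator = registry_get(reg, "rrnBT1T2", "terminator"), ...)
  promoterless <- base(orf = registry_get(reg, "eGFP", "orf"))
  expect_identical(nrow(validate_plasmid(promoterless)), 0L)
  expect_identical(length(scan_sites(promoterless, "XbaI")), 1L)
  expect_identical(length(scan_sites(promoterless, "NheI")), 1L)
  # inducible promoter without regulator is refused
  expect_error(base(promoter = registry_get(reg, "tac", "promoter"),
                    rbs = registry_get(reg, "sod", "rbs"),
                    orf = registry_get(reg, "eGFP", "orf")),
               "regulator")
  # two parts for one role is a type error at the interface
  expect_error(base(orf = registry_get(reg, "sod", "rbs")), "role")
})

test_that("validate_plasmid reports duplicated and missing sites", {
  reg <- test_registry()
  m <- test_fixtures()$backbone
  expect_identical(nrow(validate_plasmid(m)), 0L)
  # plant a stray SpeI inside the marker region
  seq2 <- sub("GCATGC", "GCATGCACTAGT", m$seq, fixed = TRUE)
  m2 <- dna(seq2, "circular", empty_features())
  rep <- validate_plasmid(m2)
  expect_true(any(rep$severity == "error" & grepl("SpeI", rep$message)))
  expect_true(any(validate_plasmid(dna("ACGT", "linear"))$code == "topology"))
})

test_that("fluorescence normalisation uses the registry brightness constants", {
  expect_identical(normalize_fluorescence(34, "eGFP"), 1)
  expect_identical(normalize_fluorescence(16, "mCherry"), 1)
  expect_identical(normalize_fluorescence(0, "eGFP"), 0)
  expect_identical(normalize_fluorescence(68, "eGFP"), 2)
  expect_error(normalize_fluorescence(10, "GFPuv"), "unknown fluorophore")
})

test_that("construct ranking is the product partial order of the metadata", {
  cmp <- function(a, b) {
    ro <- rank_constructs(data.frame(promoter = c(a[1], b[1]),
                                     rbs = c(a[2], b[2]),
                                     replicon = c(a[3], b[3]),
                                     id = c("A", "B")))
    ro$relation["A", "B"]
  }
  expect_identical(cmp(c("tac", "sod", "pGA1"), c("sod", "sod", "pGA1")), "geq")
  expect_identical(cmp(c("tac", "sod", "pGA1"), c("sod", "lacZ", "pGA1")), "geq")
  expect_identical(cmp(c("tac", "cspB", "pGA1"), c("sod", "sod", "pGA1")),
                   "incomparable")
  expect_identical(cmp(c("tac", "sod", "pGA1"), c("tac", "sod", "pCRY4")), "geq")
  expect_identical(cmp(c("tac", "sod", "pCRY4"), c("tac", "sod", "pNG2")), "eq")
  expect_error(rank_constructs(data.frame(promoter = "tac", rbs = "sod",
                                          replicon = "nosuch")),
               "unknown part id")
})
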