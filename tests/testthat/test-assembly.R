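# cloning procedures: insertion, extension, swaps, plans, series

empty_vector <- function(reg, promoter = NULL, rbs = NULL, regulator = NULL,
                         ori = "pGA1") {
  assemble_single_tu(
    host_ori = registry_get(reg, ori, "host_ori"),
    ecoli_ori = registry_get(reg, "ColE1", "ecoli_ori"),
    marker = registry_get(reg, "kan", "marker"),
    regulator = if (!is.null(regulator)) registry_get(reg, regulator, "regulator"),
    promoter = if (!is.null(promoter)) registry_get(reg, promoter, "promoter"),
    rbs = if (!is.null(rbs)) registry_get(reg, rbs, "rbs"),
    terminator = registry_get(reg, "rrnBT1T2", "terminator"))
}

test_that("ORF insertion is directional, unique-site preserving and reversible", {
  reg <- test_registry()
  vec <- empty_vector(reg, rbs = "sod") # pTGR2-like
  orf <- registry_get(reg, "eGFP", "orf")
  m <- quiet(insert_orf(vec, orf))
  expect_identical(length(scan_sites(m, "NdeI")), 1L)
  expect_identical(length(scan_sites(m, "EcoRI")), 1L)
  expect_true("orf" %in% m$features$role)
  # excising with NdeI+EcoRI recovers the flanked ORF fragment
  fr <- digest(m, c("NdeI", "EcoRI"))
  small <- fr[[which.min(vapply(fr, function(f) nchar(f$seq), 1L))]]
  ins <- ptgr:::.part_insert_fragment(orf)
  expect_identical(small$seq, ins$seq)
  # a vector with two EcoRI sites is refused
  bad <- dna(paste0("CATATG", "AA", "GAATTC", strrep("CT", 10), "GAATTC",
                    strrep("AG", 10)), "circular")
  expect_error(insert_orf(bad, orf), "unique EcoRI")
})

test_that("operon extension matches the worked two-reporter construction", {
  reg <- test_registry()
  acceptor <- quiet(insert_orf(empty_vector(reg, "tac", "sod", "lacI"),
                               registry_get(reg, "mCherry", "orf")))
  donor <- quiet(insert_orf(empty_vector(reg, "tac", "sod", "lacI"),
                            registry_get(reg, "eGFP", "orf")))
  m <- quiet(extend_operon(acceptor, donor))
  # gene order: mCherry then eGFP downstream of the single promoter
  ft <- m$features[m$features$role == "orf", ]
  L <- nchar(m$seq)
  prom <- m$features[m$features$role == "promoter", ]
  dist <- function(s) (s - prom$start[1L]) %% L
  ords <- ft$label[order(dist(ft$start))]
  expect_identical(sub("#.*$", "", ords), c("mCherry", "eGFP"))
  # site census: NheI x1, AvrII x1, NdeI x2, EcoRI x2
  cen <- ptgr:::.site_census(m)
  expect_identical(cen[["NheI"]], 1L)
  expect_identical(cen[["AvrII"]], 1L)
  expect_identical(cen[["NdeI"]], 2L)
  expect_identical(cen[["EcoRI"]], 2L)
  # dead scar present with the parent names
  expect_true(any(grepl("scar:NheI/AvrII|scar:AvrII/NheI",
                        m$features$label[m$features$role == "scar"])))
  # length additivity: product = acceptor + selected donor cassette
  cass <- ptgr:::.pick_fragment(digest(donor, c("NheI", "AvrII")),
                                c("rbs", "orf"), "cassette")
  expect_identical(nchar(m$seq), nchar(acceptor$seq) + nchar(cass$seq))
})

test_that("operon and cluster extension close recursively with the expected censuses", {
  reg <- test_registry()
  base <- quiet(insert_orf(empty_vector(reg, "tac", "sod", "lacI"),
                           registry_get(reg, "mCherry", "orf")))
  donors <- list(
    quiet(insert_orf(empty_vector(reg, rbs = "sod", regulator = "lacI"),
                     registry_get(reg, "eGFP", "orf"))),
    quiet(insert_orf(empty_vector(reg, rbs = "lacZ", regulator = "lacI"),
                     registry_get(reg, "eGFP", "orf"))))
  m <- base
  for (k in seq_along(donors)) {
    m <- quiet(extend_operon(m, donors[[k]]))
    cen <- ptgr:::.site_census(m)
    ft <- m$features
    expect_identical(sum(ft$role == "promoter"), 1L)
    expect_identical(sum(ft$role == "rbs"), k + 1L)
    expect_identical(sum(ft$role == "orf"), k + 1L)
    expect_identical(sum(ft$role == "terminator"), 1L)
    expect_identical(cen[["NheI"]], 1L)
    expect_identical(cen[["AvrII"]], 1L)
    expect_identical(cen[["NdeI"]], k + 1L)
    expect_identical(cen[["EcoRI"]], k + 1L)
  }
})

test_that("cluster extension regenerates SpeI and leaves dead joints", {
  reg <- test_registry()
  tu1 <- quiet(insert_orf(empty_vector(reg, "tac", "sod", "lacI"),
                          registry_get(reg, "eGFP", "orf")))
  tu2 <- quiet(insert_orf(empty_vector(reg, "sod", "sod", "lacI"),
                          registry_get(reg, "mCherry", "orf")))
  tu3 <- quiet(insert_orf(empty_vector(reg, "cspB", "lacZ", "lacI"),
                          registry_get(reg, "eGFP", "orf")))
  cl <- tu1
  for (d in list(tu2, tu3)) cl <- quiet(extend_cluster(cl, d))
  cen <- ptgr:::.site_census(cl)
  expect_identical(cen[["XbaI"]], 1L)
  expect_identical(cen[["SpeI"]], 1L)
  expect_identical(cen[["NheI"]], 3L)
  expect_identical(cen[["AvrII"]], 3L)
  scars <- cl$features$label[cl$features$role == "scar"]
  expect_identical(sum(grepl("scar:SpeI/XbaI", scars)), 2L) # one per interior joint
  # operon extension on the multi-TU product is refused with guidance
  don <- quiet(insert_orf(empty_vector(reg, rbs = "sod", regulator = "lacI"),
                          registry_get(reg, "eGFP", "orf")))
  expect_error(extend_operon(cl, don), "targeted assembly")
})

test_that("slot swaps replace one slot and only that slot", {
  reg <- test_registry()
  m5 <- quiet(insert_orf(empty_vector(reg, "tac", "sod", "lacI"),
                         registry_get(reg, "eGFP", "orf")))
  m17 <- quiet(swap_slot(m5, "host_ori", registry_get(reg, "pCRY4", "host_ori")))
  expect_true("pCRY4" %in% m17$features$label)
  expect_false("pGA1" %in% m17$features$label)
  expect_identical(nchar(m17$seq),
                   nchar(m5$seq) - nchar(registry_get(reg, "pGA1", "host_ori")$core_seq) +
                     nchar(registry_get(reg, "pCRY4", "host_ori")$core_seq))
  # everything else untouched: same census, other features preserved
  expect_identical(ptgr:::.site_census(m17), ptgr:::.site_census(m5))
  # identity swap returns the same plasmid under canonical rotation
  same <- quiet(swap_slot(m5, "host_ori", registry_get(reg, "pGA1", "host_ori")))
  expect_true(same_plasmid(same, m5))
  # promoter swap to an inducible promoter without regulator raises an advisory
  m3 <- quiet(insert_orf(empty_vector(reg, "sod", "sod"),
                         registry_get(reg, "eGFP", "orf")))
  expect_warning(quiet(swap_slot(m3, "promoter", registry_get(reg, "tac", "promoter"))),
                 "regulator")
})

test_that("plans allocate one stage per gene and execute to the monolithic construct", {
  reg <- test_registry()
  d_op <- ptgr_design(list(list(promoter = "tac", genes = list(
    list(orf = "mCherry", rbs = "sod"), list(orf = "eGFP", rbs = "sod")))),
    name = "op2")
  p_op <- plan_assembly(d_op, reg)
  expect_length(p_op$stages, 2L)
  expect_length(p_op$stages[[1L]], 2L) # two parallel insertions count once
  d_cl <- ptgr_design(list(
    list(promoter = "tac", genes = list(list(orf = "eGFP", rbs = "sod"))),
    list(promoter = "sod", genes = list(list(orf = "mCherry", rbs = "sod")))),
    name = "cl2")
  expect_length(plan_assembly(d_cl, reg)$stages, 2L)
  d1 <- ptgr_design(list(list(promoter = "tac",
                              genes = list(list(orf = "eGFP", rbs = "sod")))),
                    name = "one")
  expect_length(plan_assembly(d1, reg)$stages, 1L)
  # n-gene property over randomized designs
  set.seed(41)
  for (i in 1:12) {
    n_tu <- sample(1:3, 1L)
    genes_per_tu <- sample(1:2, n_tu, replace = TRUE)
    tus <- lapply(seq_len(n_tu), function(t)
      list(promoter = sample(c("sod", "cspB"), 1L),
           genes = lapply(seq_len(genes_per_tu[t]), function(g)
             list(orf = sample(c("eGFP", "mCherry"), 1L),
                  rbs = sample(c("sod", "lacZ", "cspB"), 1L)))))
    pl <- plan_assembly(ptgr_design(tus, name = "rnd"), reg)
    expect_length(pl$stages, sum(genes_per_tu))
    expect_length(pl$stages[[1L]], sum(genes_per_tu))
  }
  # executed plans reproduce monolithic assembly under canonical rotation
  m_op <- quiet(execute_plan(p_op, reg))
  expect_true(same_plasmid(m_op, assemble_design(d_op, reg)))
  expect_error(execute_plan(structure(list(stages = list(), design = d_op),
                                      class = "cloning_plan"), reg),
               "empty plan")
  expect_error(plan_assembly(ptgr_design(list(list(promoter = "nope",
    genes = list(list(orf = "eGFP", rbs = "sod")))), name = "x"), reg),
    "no promoter part")
})

test_that("the seventeen-member series builds, validates and deduplicates", {
  reg <- test_registry()
  series <- quiet(build_series(registry = reg))
  expect_length(series, 17L)
  keys <- vapply(series, canonical_rotation, character(1L))
  expect_identical(length(unique(keys)), 17L)
  for (m in series)
    expect_true(report_ok(validate_plasmid(m), errors_only = TRUE))
  # the replicon-swap route to the low-copy variant agrees with direct assembly
  m17 <- quiet(swap_slot(series$pTGR5, "host_ori",
                         registry_get(reg, "pCRY4", "host_ori")))
  expect_true(same_plasmid(m17, series$pTGR17))
  # duplicate rows collapse with a warning
  tab <- ptgr_series_table()[c(1, 1, 2), ]
  expect_warning(s <- quiet(build_series(tab, reg)), "duplicate")
  expect_length(s, 2L)
})
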