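# -- the cloning procedures as algorithms ------------------------------------

.part_roles <- function() slot_table()$role

# grammar filter helpers: every part feature on the top strand, and the site
# census matching expectation -- orientation and site bookkeeping are measured
# on the product, never assumed
.parts_forward <- function(m) {
  ft <- m$features
  all(ft$strand[ft$role %in% .part_roles()] == "+")
}

.census_matches <- function(m, want) {
  census <- .site_census(m, names(want))
  all(census == unlist(want))
}

.pick_fragment <- function(frags, has_roles, label) {
  hit <- vapply(frags, function(f) all(has_roles %in% f$features$role), logical(1L))
  if (sum(hit) != 1L)
    stop(sprintf("cannot identify the %s fragment by feature annotation (%d candidate(s))",
                 label, sum(hit)), call. = FALSE)
  frags[[which(hit)]]
}

.require_unique <- function(m, enzyme_names, who) {
  for (nm in enzyme_names) {
    n <- length(scan_sites(m, nm))
    if (n != 1L)
      stop(sprintf("%s must have a unique %s site (found %d)%s", who, nm, n,
                   if (n > 1L && nm %in% c("AvrII", "SpeI"))
                     "; multi-TU acceptors require targeted assembly, which the standard does not define"
                   else ""),
           call. = FALSE)
  }
  invisible(TRUE)
}

# the linear fragment carrying a flanked part, cut out with its slot enzymes
.part_insert_fragment <- function(p) {
  flanked <- flank_part(p)
  slot <- .slot_of(p$role)
  lstrip <- if (p$role == "orf") 3L else nchar(enz(slot$left)$recognition)
  ft <- features(p$id, p$role, lstrip, lstrip + nchar(p$core_seq))
  lin <- dna(flanked, "linear", ft, id = paste0("flanked_", p$id))
  frags <- digest(lin, c(slot$left, slot$right))
  .pick_fragment(frags, p$role, paste0("'", p$id, "' insert"))
}

# run a digestion/ligation and apply a grammar filter; exactly one product
# must survive
.one_product <- function(frag_a, frag_b, keep, step, id = NULL) {
  prods <- ligate_circular(list(frag_a, frag_b), id = id)
  ok <- Filter(keep, prods)
  if (length(ok) == 0L)
    stop("no ligation product passes the grammar filter in ", step, call. = FALSE)
  if (length(ok) > 1L)
    stop("ambiguous products pass the grammar filter in ", step, call. = FALSE)
  message(sprintf("[%s] %d chemical product(s), %d accepted, %d discarded",
                  step, length(prods), length(ok), length(prods) - length(ok)))
  annotate_sites(ok[[1L]])
}

#' Insert an ORF into a vector's NdeI-EcoRI slot
#'
#' Simulates NdeI+EcoRI digestion of the vector, keeps the backbone fragment
#' (identified by its part features, not by length), and ligates the flanked
#' ORF directionally (the TA and AATT overhangs admit a single orientation).
#' The product retains unique NdeI and EcoRI sites. Any ORF already occupying
#' the slot is replaced.
#'
#' @param vector Circular [dna()] vector with unique NdeI and EcoRI sites.
#' @param orf An ORF [part()].
#' @return The circular product.
#' @export
insert_orf <- function(vector, orf) {
  stopifnot(inherits(vector, "dna"), inherits(orf, "ptgr_part"))
  if (orf$role != "orf") stop("part must have role 'orf'", call. = FALSE)
  .require_unique(vector, c("NdeI", "EcoRI"), "vector")
  frags <- digest(vector, c("NdeI", "EcoRI"))
  backbone_roles <- setdiff(.part_roles(), c("orf", "rbs", "promoter"))
  hit <- vapply(frags, function(f) any(f$features$role %in% backbone_roles),
                logical(1L))
  if (sum(hit) != 1L)
    stop("backbone fragment not identifiable by feature annotation", call. = FALSE)
  backbone <- frags[[which(hit)]]
  insert <- .part_insert_fragment(orf)
  .one_product(backbone, insert,
               function(m) .census_matches(m, list(NdeI = 1L, EcoRI = 1L)) &&
                 .parts_forward(m),
               step = sprintf("insert_orf(%s)", orf$id),
               id = paste0(if (!is.null(vector$id)) vector$id else "vector",
                           "+", orf$id))
}

#' Extend an operon by one RBS-ORF cassette
#'
#' The recursive operon-building move of the standard: the donor's NheI-AvrII
#' cassette (carrying RBS and ORF) is excised and inserted into the
#' acceptor's unique AvrII site. NheI and AvrII leave compatible CTAG
#' cohesive ends, so two chemical orientations exist; the grammar filter
#' keeps the product whose upstream junction is the dead NheI/AvrII scar
#' (CCTAGC, separating the upstream gene's stop from the incoming RBS) and
#' whose downstream junction regenerates AvrII -- leaving NheI and AvrII
#' unique again, so the move can be applied recursively.
#'
#' @param acceptor Circular plasmid with a unique AvrII site (single-TU; a
#'   multi-TU acceptor is refused rather than guessing a target site).
#' @param donor Circular plasmid with unique NheI and AvrII sites.
#' @return The extended circular product.
#' @export
extend_operon <- function(acceptor, donor) {
  stopifnot(inherits(acceptor, "dna"), inherits(donor, "dna"))
  .require_unique(donor, c("NheI", "AvrII"), "donor")
  .require_unique(acceptor, "AvrII", "acceptor")
  cassette <- .pick_fragment(digest(donor, c("NheI", "AvrII")),
                             c("rbs", "orf"), "RBS-ORF cassette")
  open_acc <- digest(acceptor, "AvrII")[[1L]]
  n_nhei <- length(scan_sites(acceptor, "NheI"))
  .one_product(open_acc, cassette,
               function(m) .census_matches(m, list(NheI = n_nhei, AvrII = 1L)) &&
                 .parts_forward(m),
               step = "extend_operon",
               id = paste0(if (!is.null(acceptor$id)) acceptor$id else "acceptor",
                           "::op"))
}

#' Extend a gene cluster by one transcriptional unit
#'
#' The cluster-building move: the donor's XbaI-SpeI transcriptional-unit
#' cassette is excised and inserted into the acceptor's unique SpeI site.
#' The accepted product carries a dead XbaI/SpeI scar (ACTAGA) at the joint
#' and a regenerated SpeI at the far end, so XbaI and SpeI remain unique and
#' further TUs can be added recursively.
#'
#' @param acceptor Circular plasmid with a unique SpeI site.
#' @param donor Circular plasmid with unique XbaI and SpeI sites.
#' @return The extended circular product.
#' @export
extend_cluster <- function(acceptor, donor) {
  stopifnot(inherits(acceptor, "dna"), inherits(donor, "dna"))
  .require_unique(donor, c("XbaI", "SpeI"), "donor")
  .require_unique(acceptor, "SpeI", "acceptor")
  cassette <- .pick_fragment(digest(donor, c("XbaI", "SpeI")),
                             c("orf", "terminator"), "transcriptional-unit cassette")
  open_acc <- digest(acceptor, "SpeI")[[1L]]
  .one_product(open_acc, cassette,
               function(m) .census_matches(m, list(XbaI = 1L, SpeI = 1L)) &&
                 .parts_forward(m),
               step = "extend_cluster",
               id = paste0(if (!is.null(acceptor$id)) acceptor$id else "acceptor",
                           "::tu"))
}

#' Swap the content of a slot
#'
#' Excises the current slot content with the slot's flanking pair and inserts
#' the flanked new part, leaving all other features untouched. Works for any
#' of the eight roles, e.g. replicon swaps through KpnI/PstI in a single
#' cloning step. Swapping in an inducible promoter on a plasmid without a
#' regulator raises an advisory warning (the repressor cassette belongs in
#' the BamHI-BglII slot).
#'
#' @param plasmid Circular plasmid; the slot's flanking sites must be unique.
#' @param role Slot role.
#' @param new_part Replacement [part()] of that role.
#' @return The swapped circular product.
#' @export
swap_slot <- function(plasmid, role, new_part) {
  stopifnot(inherits(plasmid, "dna"), inherits(new_part, "ptgr_part"))
  if (new_part$role != role)
    stop(sprintf("part '%s' has role %s, not %s", new_part$id, new_part$role, role),
         call. = FALSE)
  slot <- .slot_of(role)
  .require_unique(plasmid, c(slot$left, slot$right), "plasmid")
  census0 <- as.list(.site_census(plasmid))
  frags <- digest(plasmid, c(slot$left, slot$right))
  other <- setdiff(.part_roles(), role)
  hit <- vapply(frags, function(f) any(f$features$role %in% other), logical(1L))
  if (sum(hit) != 1L)
    stop("backbone fragment not identifiable by feature annotation", call. = FALSE)
  backbone <- frags[[which(hit)]]
  insert <- .part_insert_fragment(new_part)
  out <- .one_product(backbone, insert,
                      function(m) .census_matches(m, census0) && .parts_forward(m),
                      step = sprintf("swap_slot(%s<-%s)", role, new_part$id),
                      id = paste0(if (!is.null(plasmid$id)) plasmid$id else "plasmid",
                                  "::", role, "=", new_part$id))
  if (role == "promoter" && isTRUE(new_part$meta$inducible) &&
      !any(out$features$role == "regulator"))
    warning(sprintf("promoter '%s' is inducible but the plasmid carries no regulator cassette (BamHI-BglII slot)",
                    new_part$id), call. = FALSE)
  out
}

# -- cloning plans -------------------------------------------------------------

#' A single cloning step
#' @param kind One of insert_orf, transfer_operon_cassette, transfer_tu, swap_slot.
#' @param donor,acceptor Construct/part ids.
#' @param product Id of the expected product.
#' @param payload Kind-specific parameters.
#' @return Object of class `cloning_step`.
#' @export
cloning_step <- function(kind = c("insert_orf", "transfer_operon_cassette",
                                  "transfer_tu", "swap_slot"),
                         donor, acceptor, product, payload = list()) {
  kind <- match.arg(kind)
  enzymes_used <- switch(kind,
                         insert_orf = c("NdeI", "EcoRI"),
                         transfer_operon_cassette = c("NheI", "AvrII"),
                         transfer_tu = c("XbaI", "SpeI"),
                         swap_slot = payload$enzymes)
  structure(list(kind = kind, donor = donor, acceptor = acceptor,
                 enzymes = enzymes_used, product = product, payload = payload),
            class = "cloning_step")
}

#' Plan the construction of a multi-gene design
#'
#' Stage 1 inserts every gene of the design into its own configured
#' single-TU vector in parallel; each later stage is one cassette transfer
#' (operon extension within a TU, then TU transfers between clusters). A
#' cloning step is a stage -- parallel clonings count once -- so a design of
#' n genes is always built in exactly n stages: a two-gene operon and a
#' two-TU cluster each take two cloning steps.
#'
#' @param design A [ptgr_design()].
#' @param registry A `part_registry` resolving every referenced part id.
#' @return Object of class `cloning_plan`.
#' @export
plan_assembly <- function(design, registry = default_registry()) {
  stopifnot(inherits(design, "ptgr_design"))
  # resolve every referenced part now so missing ids fail at plan time
  for (tu in design$tus) {
    if (!is.na(tu$promoter)) registry_get(registry, tu$promoter, "promoter")
    for (g in tu$genes) {
      registry_get(registry, g$orf, "orf")
      if (!is.na(g$rbs)) registry_get(registry, g$rbs, "rbs")
    }
  }
  registry_get(registry, design$replicon, "host_ori")

  inserts <- list()
  transfers <- list()
  tu_final <- character(length(design$tus))
  for (i in seq_along(design$tus)) {
    tu <- design$tus[[i]]
    gene_prod <- character(length(tu$genes))
    for (j in seq_along(tu$genes)) {
      g <- tu$genes[[j]]
      pid <- sprintf("tu%d_g%d", i, j)
      gene_prod[j] <- pid
      inserts[[length(inserts) + 1L]] <- cloning_step(
        "insert_orf", donor = g$orf, acceptor = sprintf("vector_%s", pid),
        product = pid,
        payload = list(tu = i, gene = j, orf = g$orf, rbs = g$rbs,
                       promoter = if (j == 1L) tu$promoter else NA_character_))
    }
    acc <- gene_prod[1L]
    for (j in seq_along(tu$genes)[-1L]) {
      prod <- sprintf("tu%d_op%d", i, j)
      transfers[[length(transfers) + 1L]] <- cloning_step(
        "transfer_operon_cassette", donor = gene_prod[j], acceptor = acc,
        product = prod)
      acc <- prod
    }
    tu_final[i] <- acc
  }
  acc <- tu_final[1L]
  for (i in seq_along(design$tus)[-1L]) {
    prod <- sprintf("cluster%d", i)
    transfers[[length(transfers) + 1L]] <- cloning_step(
      "transfer_tu", donor = tu_final[i], acceptor = acc, product = prod)
    acc <- prod
  }
  stages <- c(list(inserts), lapply(transfers, list))
  n_genes <- sum(vapply(design$tus, function(t) length(t$genes), 1L))
  stopifnot(length(stages) == n_genes)
  structure(list(stages = stages, design = design, final = acc),
            class = "cloning_plan")
}

#' @export
print.cloning_plan <- function(x, ...) {
  cat(sprintf("<cloning plan for '%s': %d stage(s)>\n", x$design$name,
              length(x$stages)))
  for (s in seq_along(x$stages)) {
    steps <- x$stages[[s]]
    cat(sprintf("  stage %d:\n", s))
    for (st in steps)
      cat(sprintf("    %-26s %s -> %s  [%s]  => %s\n", st$kind, st$donor,
                  st$acceptor, paste(st$enzymes, collapse = "+"), st$product))
  }
  invisible(x)
}

# assemble the configured empty vector for one planned gene
.stage1_vector <- function(step, design, registry, with_regulator) {
  pl <- step$payload
  assemble_single_tu(
    host_ori = registry_get(registry, design$replicon, "host_ori"),
    ecoli_ori = registry_get(registry, "ColE1", "ecoli_ori"),
    marker = registry_get(registry, "kan", "marker"),
    regulator = if (with_regulator) registry_get(registry, "lacI", "regulator"),
    promoter = if (!is.na(pl$promoter)) registry_get(registry, pl$promoter, "promoter"),
    rbs = if (!is.na(pl$rbs)) registry_get(registry, pl$rbs, "rbs"),
    terminator = registry_get(registry, "rrnBT1T2", "terminator"),
    id = step$acceptor)
}

.design_needs_regulator <- function(design, registry) {
  any(vapply(design$tus, function(tu) {
    if (is.na(tu$promoter)) return(FALSE)
    isTRUE(registry_get(registry, tu$promoter, "promoter")$meta$inducible)
  }, logical(1L)))
}

#' Virtually execute a cloning plan
#'
#' Runs every step through the digestion/ligation simulator, stage by stage.
#' The final product must pass [validate_plasmid()] without errors; it is
#' also identical, under canonical rotation, to the construct assembled
#' monolithically from the same parts (see [assemble_design()]) -- the two
#' code paths cross-check each other.
#'
#' @param plan A `cloning_plan` from [plan_assembly()].
#' @param registry A `part_registry`.
#' @return The final circular [dna()] product.
#' @export
execute_plan <- function(plan, registry = default_registry()) {
  stopifnot(inherits(plan, "cloning_plan"))
  if (!length(plan$stages) || !length(plan$stages[[1L]]))
    stop("empty plan", call. = FALSE)
  design <- plan$design
  with_reg <- .design_needs_regulator(design, registry)
  made <- new.env(parent = emptyenv())
  for (s in seq_along(plan$stages)) {
    for (st in plan$stages[[s]]) {
      prod <- switch(st$kind,
        insert_orf = {
          vec <- .stage1_vector(st, design, registry, with_reg)
          insert_orf(vec, registry_get(registry, st$donor, "orf"))
        },
        transfer_operon_cassette = {
          .step_input(made, st) # validates donor/acceptor exist
          extend_operon(get(st$acceptor, envir = made), get(st$donor, envir = made))
        },
        transfer_tu = {
          .step_input(made, st)
          extend_cluster(get(st$acceptor, envir = made), get(st$donor, envir = made))
        },
        stop("plan step kind not executable: ", st$kind, call. = FALSE))
      assign(st$product, prod, envir = made)
    }
  }
  final <- get(plan$final, envir = made)
  rep <- validate_plasmid(final)
  if (!report_ok(rep, errors_only = TRUE))
    stop("executed plan fails plasmid validation:\n",
         paste(utils::capture.output(print(rep)), collapse = "\n"), call. = FALSE)
  final$id <- design$name
  final
}

.step_input <- function(made, st) {
  for (need in c(st$donor, st$acceptor))
    if (!exists(need, envir = made))
      stop(sprintf("step '%s' needs '%s' before its stage", st$product, need),
           call. = FALSE)
}

#' Assemble a design monolithically (no simulation)
#'
#' Writes down the final sequence of a multi-gene construct directly from
#' the grammar: transcriptional units joined by dead XbaI/SpeI scars
#' (ACTAGA), genes within an operon joined by dead NheI/AvrII scars
#' (CCTAGC), standard flanks and backbone in slot order. Used as the
#' independent reference for [execute_plan()].
#'
#' @param design A [ptgr_design()].
#' @param registry A `part_registry`.
#' @return Circular [dna()] plasmid.
#' @export
assemble_design <- function(design, registry = default_registry()) {
  stopifnot(inherits(design, "ptgr_design"))
  core <- function(id, role) registry_get(registry, id, role)$core_seq
  with_reg <- .design_needs_regulator(design, registry)
  seq <- "TCTAGA"
  ft <- empty_features()
  addft <- function(ft, id, role, at, len) rbind(ft, features(id, role, at, at + len))
  for (i in seq_along(design$tus)) {
    tu <- design$tus[[i]]
    if (i > 1L) seq <- paste0(seq, "ACTAGA") # dead XbaI/SpeI scar between TUs
    if (!is.na(tu$promoter)) {
      ft <- addft(ft, tu$promoter, "promoter", nchar(seq), nchar(core(tu$promoter, "promoter")))
      seq <- paste0(seq, core(tu$promoter, "promoter"))
    }
    seq <- paste0(seq, "GCTAGC")
    for (j in seq_along(tu$genes)) {
      g <- tu$genes[[j]]
      if (j > 1L) seq <- paste0(seq, "CCTAGC") # dead NheI/AvrII scar between genes
      if (!is.na(g$rbs)) {
        ft <- addft(ft, g$rbs, "rbs", nchar(seq), nchar(core(g$rbs, "rbs")))
        seq <- paste0(seq, core(g$rbs, "rbs"))
      }
      seq <- paste0(seq, "CAT")
      ft <- addft(ft, g$orf, "orf", nchar(seq), nchar(core(g$orf, "orf")))
      seq <- paste0(seq, core(g$orf, "orf"), "GAATTC", .SPACER)
    }
    seq <- paste0(seq, "CCTAGG")
    ft <- addft(ft, "rrnBT1T2", "terminator", nchar(seq), nchar(core("rrnBT1T2", "terminator")))
    seq <- paste0(seq, core("rrnBT1T2", "terminator"))
  }
  seq <- paste0(seq, "ACTAGT", "GGATCC")
  if (with_reg) {
    ft <- addft(ft, "lacI", "regulator", nchar(seq), nchar(core("lacI", "regulator")))
    seq <- paste0(seq, core("lacI", "regulator"))
  }
  seq <- paste0(seq, "AGATCT")
  ft <- addft(ft, "ColE1", "ecoli_ori", nchar(seq), nchar(core("ColE1", "ecoli_ori")))
  seq <- paste0(seq, core("ColE1", "ecoli_ori"), "GCATGC")
  ft <- addft(ft, "kan", "marker", nchar(seq), nchar(core("kan", "marker")))
  seq <- paste0(seq, core("kan", "marker"), "CTGCAG")
  ft <- addft(ft, design$replicon, "host_ori", nchar(seq), nchar(core(design$replicon, "host_ori")))
  seq <- paste0(seq, core(design$replicon, "host_ori"), "GGTACC")
  ft <- .uniquify_labels(ft)
  annotate_sites(dna(seq, "circular", ft, id = design$name))
}

# -- the characterised construct series ---------------------------------------

#' The characterised pTGR construct series
#'
#' The seventeen promoter/RBS/gene/replicon combinations of the platform's
#' validation series, including the dual-gene operon and dual-TU cluster
#' formats. Slash-separated fields list per-gene (operon) or per-TU
#' (cluster) choices in construct order.
#'
#' @return Data frame with columns name, format, promoters, rbss, genes,
#'   replicon.
#' @export
ptgr_series_table <- function() {
  data.frame(
    name = paste0("pTGR", 1:17),
    format = c(rep("single", 7L), "operon", "cluster", rep("operon", 3L),
               rep("cluster", 3L), "single", "single"),
    promoters = c(NA, NA, "sod", "cspB", "tac", "tac", "tac",
                  "tac", "tac/sod", "tac", "tac", "tac",
                  "sod/tac", "tac/cspB", "cspB/tac", "tac", "tac"),
    rbss = c(NA, "sod", "sod", "sod", "sod", "lacZ", "cspB",
             "sod/sod", "sod/sod", "lacZ/sod", "lacZ/lacZ", "sod/lacZ",
             "sod/sod", "sod/sod", "sod/sod", "sod", "sod"),
    genes = c(rep("eGFP", 7L), "mCherry/eGFP", "eGFP/mCherry",
              "mCherry/eGFP", "mCherry/eGFP", "mCherry/eGFP",
              "eGFP/mCherry", "eGFP/mCherry", "eGFP/mCherry", "eGFP", "eGFP"),
    replicon = c(rep("pGA1", 15L), "pNG2", "pCRY4"),
    stringsAsFactors = FALSE)
}

.split_slash <- function(x) if (is.na(x)) NA_character_ else strsplit(x, "/", fixed = TRUE)[[1L]]

# one series row -> a design
.row_design <- function(row) {
  proms <- .split_slash(row$promoters)
  rbss <- .split_slash(row$rbss)
  genes <- .split_slash(row$genes)
  if (row$format == "cluster") {
    tus <- lapply(seq_along(genes), function(i)
      list(promoter = proms[i],
           genes = list(list(orf = genes[i], rbs = rbss[i]))))
  } else {
    tus <- list(list(promoter = proms[1L],
                     genes = lapply(seq_along(genes), function(i)
                       list(orf = genes[i], rbs = rbss[i]))))
  }
  ptgr_design(tus, replicon = row$replicon, name = row$name)
}

#' Build a combinatorial construct series
#'
#' Plans and virtually executes one construct per combination row,
#' deterministically named; duplicate combinations are deduplicated with a
#' warning. The default input is the seventeen-member characterised series.
#'
#' @param combos Data frame in the shape of [ptgr_series_table()].
#' @param registry A `part_registry`.
#' @return Named list of validated circular plasmids, class `ptgr_series`.
#' @export
build_series <- function(combos = ptgr_series_table(),
                         registry = default_registry()) {
  keys <- with(combos, paste(format, promoters, rbss, genes, replicon))
  if (anyDuplicated(keys)) {
    warning("duplicate combination row(s) dropped: ",
            paste(combos$name[duplicated(keys)], collapse = ", "), call. = FALSE)
    combos <- combos[!duplicated(keys), , drop = FALSE]
  }
  out <- lapply(seq_len(nrow(combos)), function(i) {
    design <- .row_design(combos[i, ])
    execute_plan(plan_assembly(design, registry), registry)
  })
  names(out) <- combos$name
  structure(out, class = "ptgr_series")
}

#' @export
print.ptgr_series <- function(x, ...) {
  cat(sprintf("<construct series: %d plasmid(s)>\n", length(x)))
  for (nm in names(x))
    cat(sprintf("  %-8s %d bp\n", nm, nchar(x[[nm]]$seq)))
  invisible(x)
}
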