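# -- the pTGR slot grammar ----------------------------------------------------

#' The eight-slot flanking contract
#'
#' Every part class of the standard is bounded by a fixed pair of unique
#' restriction sites: promoter XbaI-NheI, RBS NheI-NdeI, ORF NdeI-EcoRI,
#' terminator AvrII-SpeI inside the transcriptional-unit cassette
#' (itself XbaI-SpeI); regulator BamHI-BglII, E. coli origin BglII-SphI,
#' selectable marker SphI-PstI and host replication origin PstI-KpnI on the
#' backbone.
#'
#' @return Data frame with columns role, left, right (enzyme names).
#' @export
slot_table <- function() {
  data.frame(
    role  = c("regulator", "ecoli_ori", "marker", "host_ori",
              "promoter", "rbs", "orf", "terminator"),
    left  = c("BamHI", "BglII", "SphI", "PstI", "XbaI", "NheI", "NdeI", "AvrII"),
    right = c("BglII", "SphI", "PstI", "KpnI", "NheI", "NdeI", "EcoRI", "SpeI"),
    stringsAsFactors = FALSE)
}

# flanks of a whole transcriptional unit
.tu_flanks <- function() c(left = "XbaI", right = "SpeI")

# fixed 6 nt neutral spacer joining EcoRI to AvrII, free of all shipped sites
# in its assembled context
.SPACER <- "TTAACT"

.slot_of <- function(role) {
  st <- slot_table()
  i <- match(role, st$role)
  if (is.na(i)) stop("unknown part role: ", role, call. = FALSE)
  st[i, ]
}

.TU_ROLES <- c("promoter", "rbs", "orf", "terminator")

# -- part metadata ------------------------------------------------------------

#' The shipped part-strength metadata registry
#'
#' Relative strengths and physical constants of the characterised parts:
#' promoter ranks tac = high, cspB = medium, sod = low; RBS ranks
#' sod = high, lacZ = medium, cspB = low; replicon copy numbers pGA1 ~30
#' per cell, pCRY4 and pNG2 1-2 per cell; fluorophore brightness
#' eGFP = 34 and mCherry = 16 (1/(mM*cm)).
#'
#' @return Data frame with columns id, kind, strength_rank, copy_lo, copy_hi,
#'   brightness, native_spacing, inducible.
#' @export
part_metadata <- function() {
  data.frame(
    id = c("tac", "cspB", "sod",          # promoters
           "sod", "lacZ", "cspB",         # RBSs
           "pGA1", "pCRY4", "pNG2",       # host replicons
           "eGFP", "mCherry"),            # fluorophores
    kind = c(rep("promoter", 3L), rep("rbs", 3L), rep("replicon", 3L),
             rep("fluorophore", 2L)),
    strength_rank = c("high", "medium", "low",
                      "high", "medium", "low",
                      "medium", "low", "low",
                      NA, NA),
    copy_lo = c(rep(NA_integer_, 6L), 30L, 1L, 1L, NA, NA),
    copy_hi = c(rep(NA_integer_, 6L), 30L, 2L, 2L, NA, NA),
    brightness = c(rep(NA_real_, 9L), 34, 16),
    native_spacing = c(NA, NA, NA, 7L, 8L, 9L, rep(NA, 5L)),
    inducible = c(TRUE, FALSE, FALSE, rep(NA, 8L)),
    stringsAsFactors = FALSE)
}

.meta_row <- function(id, kind) {
  md <- part_metadata()
  i <- which(md$id == id & md$kind == kind)
  if (!length(i)) return(NULL)
  as.list(md[i[1L], ])
}

#' Normalise a raw fluorescence reading by fluorophore brightness
#'
#' Puts readings from different fluorophores on a comparable scale by
#' dividing arbitrary-unit fluorescence by the protein's brightness
#' (eGFP 34, mCherry 16, in 1/(mM*cm)).
#'
#' @param raw Numeric raw fluorescence, arbitrary units.
#' @param protein Fluorophore id present in the metadata registry.
#' @return Normalised value(s).
#' @export
normalize_fluorescence <- function(raw, protein) {
  stopifnot(is.numeric(raw))
  m <- .meta_row(protein, "fluorophore")
  if (is.null(m) || is.na(m$brightness))
    stop("unknown fluorophore: ", protein, call. = FALSE)
  raw / m$brightness
}

# -- parts --------------------------------------------------------------------

#' Construct a biological part
#'
#' `core_seq` excludes the flanking sites the slot contract adds. ORF cores
#' start at their ATG (the upstream flank supplies the CAT of the NdeI site)
#' and include their own stop codon.
#'
#' @param id Part identifier.
#' @param role One of the eight roles in [slot_table()].
#' @param core_seq Core sequence without flanks.
#' @param meta Optional named list of metadata (strength_rank, copy_lo,
#'   copy_hi, brightness, native_spacing, inducible); defaults come from
#'   [part_metadata()] when the id is known.
#' @return Object of class `ptgr_part`.
#' @export
part <- function(id, role, core_seq, meta = NULL) {
  .slot_of(role) # validates role
  .check_seq(core_seq, paste0("core of part '", id, "'"))
  if (is.null(meta)) {
    kind <- if (role == "host_ori") "replicon" else role
    meta <- .meta_row(id, kind)
  }
  structure(list(id = id, role = role, core_seq = core_seq,
                 meta = if (is.null(meta)) list() else meta),
            class = "ptgr_part")
}

#' @export
print.ptgr_part <- function(x, ...) {
  cat(sprintf("<part '%s' role=%s %d bp%s>\n", x$id, x$role, nchar(x$core_seq),
              if (!is.null(x$meta$strength_rank) && !is.na(x$meta$strength_rank))
                paste0(" rank=", x$meta$strength_rank) else ""))
  invisible(x)
}

# -- validation reports -------------------------------------------------------

.report <- function(severity = character(), code = character(),
                    position = integer(), message = character()) {
  structure(data.frame(severity = severity, code = code,
                       position = as.integer(position), message = message,
                       stringsAsFactors = FALSE),
            class = c("validation_report", "data.frame"))
}

.add_finding <- function(rep, severity, code, position, message) {
  rbind(rep, .report(severity, code, position, message))
}

#' Is a validation report clean?
#' @param rep A `validation_report`.
#' @param errors_only Count only error-severity findings.
#' @return Logical.
#' @export
report_ok <- function(rep, errors_only = FALSE) {
  if (errors_only) !any(rep$severity == "error") else nrow(rep) == 0L
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("<validation report: clean>\n")
  } else {
    cat(sprintf("<validation report: %d finding(s)>\n", nrow(x)))
    for (i in seq_len(nrow(x)))
      cat(sprintf("  [%s] %s @%s: %s\n", x$severity[i], x$code[i],
                  ifelse(is.na(x$position[i]), "-", x$position[i]), x$message[i]))
  }
  invisible(x)
}

# findings for shipped sites occurring in a sequence; `severe` names the
# enzymes reported as errors, others as warnings
.site_findings <- function(seq, severe, rep, where = "core") {
  for (e in enzymes()) {
    pos <- .scan_seq(seq, e$recognition)
    for (p in pos) {
      sev <- if (e$name %in% severe) "error" else "warning"
      rep <- .add_finding(rep, sev, "internal_site", p,
                          sprintf("%s site (%s) inside %s at position %d",
                                  e$name, e$recognition, where, p))
    }
  }
  rep
}

#' Validate a part against the slot grammar
#'
#' Checks the core for forbidden internal restriction sites (the six cassette
#' sites are errors for transcriptional-unit roles, as are the slot's own
#' flanking sites for every role; the remaining shipped sites are warnings
#' since they break plasmid-wide uniqueness), plus role-specific rules:
#' ORFs must start with ATG, end with a stop codon, be in frame and free of
#' internal in-frame stops; an RBS whose declared native SD-to-ATG spacing
#' disagrees with the measured distance of its Shine-Dalgarno motif gets a
#' warning (the standard preserves native spacing exactly).
#'
#' @param p A [part()].
#' @return A `validation_report` (empty iff valid), ordered by position.
#' @export
validate_part <- function(p) {
  stopifnot(inherits(p, "ptgr_part"))
  slot <- .slot_of(p$role)
  rep <- .report()
  severe <- unique(c(if (p$role %in% .TU_ROLES) cassette_enzymes(),
                     slot$left, slot$right))
  rep <- .site_findings(p$core_seq, severe, rep,
                        where = sprintf("%s core '%s'", p$role, p$id))
  if (p$role == "orf") rep <- .orf_findings(p, rep)
  if (p$role == "rbs") rep <- .rbs_findings(p, rep)
  rep <- rep[order(is.na(rep$position), rep$position), , drop = FALSE]
  rownames(rep) <- NULL
  rep
}

.STOPS <- c("TAA", "TAG", "TGA")

.orf_findings <- function(p, rep) {
  s <- p$core_seq
  n <- nchar(s)
  if (substr(s, 1L, 3L) != "ATG")
    rep <- .add_finding(rep, "error", "orf_start", 0L, "ORF core must start with ATG")
  if (n %% 3L != 0L)
    rep <- .add_finding(rep, "error", "orf_frame", n,
                        "ORF core length must be divisible by 3")
  else {
    codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
    if (!(codons[length(codons)] %in% .STOPS))
      rep <- .add_finding(rep, "error", "orf_stop", n - 3L,
                          "ORF core must end with a stop codon")
    internal <- which(codons[-length(codons)] %in% .STOPS)
    for (i in internal)
      rep <- .add_finding(rep, "error", "orf_internal_stop", (i - 1L) * 3L,
                          sprintf("internal stop codon %s in frame 0", codons[i]))
  }
  rep
}

# SD located as the last AGGAG in the core; measured spacing counts from the
# 3' end of the motif to the ATG supplied with the NdeI flank (CAT + ATG)
.rbs_findings <- function(p, rep) {
  spacing <- p$meta$native_spacing
  sd <- .scan_seq(p$core_seq, "AGGAG")
  if (!length(sd)) {
    rep <- .add_finding(rep, "info", "rbs_no_sd", NA_integer_,
                        "no Shine-Dalgarno motif (AGGAG) located in RBS core")
    return(rep)
  }
  measured <- nchar(p$core_seq) - (max(sd) + 5L) + 3L
  if (!is.null(spacing) && !is.na(spacing) && measured != spacing)
    rep <- .add_finding(rep, "warning", "rbs_spacing", max(sd),
                        sprintf("measured SD->ATG spacing %d differs from declared native spacing %d",
                                measured, spacing))
  rep
}

# -- flanking -----------------------------------------------------------------

#' Add a part's slot flanks
#'
#' Returns `left_site + core + right_site` per the slot contract. For ORFs the
#' ATG is embedded in the NdeI site: the upstream flank contributes only CAT,
#' so the junction reads CATATG with the start codon in frame. Errors if the
#' part does not validate or if flanking creates a duplicate shipped site at
#' a boundary.
#'
#' @param p A [part()].
#' @return Flanked nucleotide text.
#' @export
flank_part <- function(p) {
  rep <- validate_part(p)
  if (!report_ok(rep, errors_only = TRUE))
    stop("part '", p$id, "' fails validation:\n",
         paste(utils::capture.output(print(rep)), collapse = "\n"), call. = FALSE)
  slot <- .slot_of(p$role)
  left <- enz(slot$left)$recognition
  if (p$role == "orf") left <- "CAT" # core's ATG completes the NdeI site
  flanked <- paste0(left, p$core_seq, enz(slot$right)$recognition)
  expected <- table(c(slot$left, slot$right))
  for (e in enzymes()) {
    n <- length(.scan_seq(flanked, e$recognition))
    want <- if (e$name %in% names(expected)) as.integer(expected[[e$name]]) else 0L
    if (n > want)
      stop(sprintf("flanking part '%s' creates a duplicate %s site at a boundary",
                   p$id, e$name), call. = FALSE)
  }
  flanked
}

#' Recover a part core from its flanked sequence
#'
#' Inverse of [flank_part()]: strips the slot's flanking sites (for ORFs only
#' the CAT contributed by the NdeI flank).
#'
#' @param flanked Flanked sequence.
#' @param role Part role.
#' @return The core sequence.
#' @export
excise_core <- function(flanked, role) {
  slot <- .slot_of(role)
  lstrip <- if (role == "orf") 3L else nchar(enz(slot$left)$recognition)
  rstrip <- nchar(enz(slot$right)$recognition)
  .substr0(flanked, lstrip, nchar(flanked) - rstrip)
}

# -- single-TU assembly -------------------------------------------------------

#' Assemble a single-transcriptional-unit plasmid
#'
#' Builds the generic eight-slot circular plasmid: the XbaI...SpeI
#' transcriptional-unit cassette (promoter, RBS, ORF, terminator, with a
#' fixed neutral 6 nt linker joining EcoRI to AvrII) followed by the backbone
#' (regulator, E. coli origin, marker, host origin), every one of the eleven
#' standard sites occurring exactly once. Promoter, RBS and ORF slots may be
#' omitted (`NULL`), giving the promoterless / empty-slot control forms whose
#' flanking sites are retained. A promoter whose metadata marks it inducible
#' (e.g. tac, repressed by LacI) requires the regulator slot to be filled.
#'
#' @param host_ori,ecoli_ori,marker,terminator Required [part()]s.
#' @param regulator,promoter,rbs,orf Optional [part()]s.
#' @param id Optional plasmid id.
#' @return Circular [dna()] plasmid with part, linker and site features.
#' @export
assemble_single_tu <- function(host_ori, ecoli_ori, marker,
                               regulator = NULL, promoter = NULL, rbs = NULL,
                               orf = NULL, terminator, id = NULL) {
  given <- list(host_ori = host_ori, ecoli_ori = ecoli_ori, marker = marker,
                regulator = regulator, promoter = promoter, rbs = rbs,
                orf = orf, terminator = terminator)
  for (role in names(given)) {
    p <- given[[role]]
    if (is.null(p)) next
    if (!inherits(p, "ptgr_part")) stop(role, " must be a part", call. = FALSE)
    if (p$role != role)
      stop(sprintf("part '%s' has role %s but was supplied for the %s slot",
                   p$id, p$role, role), call. = FALSE)
    rep <- validate_part(p)
    if (!report_ok(rep, errors_only = TRUE))
      stop("part '", p$id, "' fails validation:\n",
           paste(utils::capture.output(print(rep)), collapse = "\n"), call. = FALSE)
  }
  if (!is.null(promoter) && isTRUE(promoter$meta$inducible) && is.null(regulator))
    stop(sprintf("promoter '%s' is inducible and requires a regulator part",
                 promoter$id), call. = FALSE)

  core <- function(p) if (is.null(p)) "" else p$core_seq
  pieces <- list(
    list(site = "XbaI"), list(part = promoter, role = "promoter"),
    list(site = "NheI"), list(part = rbs, role = "rbs"),
    list(lit = if (is.null(orf)) "CATATG" else "CAT", label = "NdeI_flank"),
    list(part = orf, role = "orf"),
    list(site = "EcoRI"), list(lit = .SPACER, label = "linker", role = "linker"),
    list(site = "AvrII"), list(part = terminator, role = "terminator"),
    list(site = "SpeI"),
    list(site = "BamHI"), list(part = regulator, role = "regulator"),
    list(site = "BglII"), list(part = ecoli_ori, role = "ecoli_ori"),
    list(site = "SphI"), list(part = marker, role = "marker"),
    list(site = "PstI"), list(part = host_ori, role = "host_ori"),
    list(site = "KpnI"))

  seq <- ""; ft <- empty_features()
  for (pc in pieces) {
    at <- nchar(seq)
    if (!is.null(pc$site)) {
      seq <- paste0(seq, enz(pc$site)$recognition)
    } else if (!is.null(pc$lit)) {
      if (identical(pc$label, "linker"))
        ft <- rbind(ft, features("linker", "linker", at, at + nchar(pc$lit)))
      seq <- paste0(seq, pc$lit)
    } else if (!is.null(pc$part)) {
      p <- pc$part
      ft <- rbind(ft, features(p$id, p$role, at, at + nchar(p$core_seq)))
      seq <- paste0(seq, p$core_seq)
    }
  }
  m <- dna(seq, "circular", .uniquify_labels(ft), id = id)

  census <- .site_census(m)
  bad <- census != 1L
  if (any(bad)) {
    msgs <- vapply(names(census)[bad], function(n)
      sprintf("%s x%d at %s", n, census[[n]],
              paste(scan_sites(m, n), collapse = ",")), character(1L))
    stop("assembled plasmid violates site uniqueness: ",
         paste(msgs, collapse = "; "), call. = FALSE)
  }
  annotate_sites(m)
}

# -- plasmid validation -------------------------------------------------------

#' Audit a plasmid against the pTGR standard
#'
#' Report-based (never throws): audits the census of the eleven standard
#' sites against the plasmid's structure. XbaI and SpeI must always be unique
#' (duplication breaks cluster extension, error); NheI/AvrII must be unique
#' per transcriptional unit and NdeI/EcoRI unique per gene -- counts matching
#' a multi-TU/multi-gene structure are reported as info, mismatches as
#' errors. Backbone sites must be unique. The scar inventory is reported as
#' info findings.
#'
#' @param m Circular [dna()] plasmid.
#' @return A `validation_report`.
#' @export
validate_plasmid <- function(m) {
  stopifnot(inherits(m, "dna"))
  rep <- .report()
  if (!.is_circular(m)) {
    return(.add_finding(rep, "error", "topology", NA_integer_,
                        "plasmid must be circular"))
  }
  ft <- m$features
  n_tu <- max(1L, sum(ft$role == "terminator"))
  n_gene <- max(1L, sum(ft$role == "orf"))
  census <- .site_census(m)
  expected <- c(XbaI = 1L, SpeI = 1L, NheI = n_tu, AvrII = n_tu,
                NdeI = n_gene, EcoRI = n_gene,
                BamHI = 1L, BglII = 1L, SphI = 1L, PstI = 1L, KpnI = 1L)
  for (nm in names(expected)) {
    n <- census[[nm]]
    want <- expected[[nm]]
    pos <- paste(scan_sites(m, nm), collapse = ",")
    if (n != want) {
      rep <- .add_finding(rep, "error", "site_census", scan_sites(m, nm)[1L],
                          sprintf("%s expected x%d, found x%d (at %s)", nm, want, n, pos))
    } else if (n > 1L) {
      rep <- .add_finding(rep, "info", "multi_tu_site", scan_sites(m, nm)[1L],
                          sprintf("%s x%d as expected for a %d-TU / %d-gene construct",
                                  nm, n, n_tu, n_gene))
    }
  }
  scars <- ft[ft$role == "scar", , drop = FALSE]
  for (i in seq_len(nrow(scars)))
    rep <- .add_finding(rep, "info", "scar", scars$start[i],
                        sprintf("%s (%s)", scars$label[i],
                                .substr_circ(m$seq, scars$start[i],
                                             scars$end[i] - scars$start[i])))
  rep <- rep[order(is.na(rep$position), rep$position), , drop = FALSE]
  rownames(rep) <- NULL
  rep
}

# -- construct partial order --------------------------------------------------

#' Compare constructs by part-strength ranks
#'
#' A construct dominates another iff its promoter rank, RBS rank and replicon
#' copy number are all at least as high; conflicting ranks are incomparable.
#' No numeric expression level is predicted -- the order is purely the partial
#' order induced by the shipped strength metadata. Constructs using unranked
#' parts are excluded with a warning.
#'
#' @param constructs Data frame with columns `promoter`, `rbs`, `replicon`
#'   (part ids), optionally `id`.
#' @return Object of class `construct_order`: list with the comparison matrix
#'   (entries "geq", "leq", "eq", "incomparable"), the scored table, and ids
#'   of excluded constructs.
#' @export
rank_constructs <- function(constructs) {
  stopifnot(is.data.frame(constructs),
            all(c("promoter", "rbs", "replicon") %in% names(constructs)))
  ids <- if ("id" %in% names(constructs)) constructs$id
         else sprintf("(%s,%s,%s)", constructs$promoter, constructs$rbs,
                      constructs$replicon)
  rank_num <- c(high = 3, medium = 2, low = 1)
  score1 <- function(id, kind) {
    m <- .meta_row(id, kind)
    if (is.null(m)) stop("unknown part id: ", id, call. = FALSE)
    if (kind == "replicon") {
      if (is.na(m$copy_lo)) return(NA_real_)
      return((m$copy_lo + m$copy_hi) / 2)
    }
    if (is.na(m$strength_rank) || !m$strength_rank %in% names(rank_num))
      return(NA_real_)
    rank_num[[m$strength_rank]]
  }
  sc <- data.frame(id = ids,
                   p = vapply(constructs$promoter, score1, numeric(1L), "promoter"),
                   r = vapply(constructs$rbs, score1, numeric(1L), "rbs"),
                   c = vapply(constructs$replicon, score1, numeric(1L), "replicon"),
                   stringsAsFactors = FALSE)
  excluded <- sc$id[!stats::complete.cases(sc[, c("p", "r", "c")])]
  if (length(excluded))
    warning("excluded from the order (unranked part): ",
            paste(excluded, collapse = ", "), call. = FALSE)
  keep <- sc[!sc$id %in% excluded, , drop = FALSE]
  n <- nrow(keep)
  rel <- matrix("incomparable", n, n, dimnames = list(keep$id, keep$id))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- as.numeric(keep[i, c("p", "r", "c")])
    b <- as.numeric(keep[j, c("p", "r", "c")])
    rel[i, j] <- if (all(a == b)) "eq"
    else if (all(a >= b)) "geq"
    else if (all(a <= b)) "leq"
    else "incomparable"
  }
  structure(list(relation = rel, scores = keep, excluded = excluded),
            class = "construct_order")
}

#' @export
print.construct_order <- function(x, ...) {
  cat(sprintf("<construct partial order over %d construct(s)>\n", nrow(x$scores)))
  print(x$relation, quote = FALSE)
  if (length(x$excluded))
    cat("excluded (unranked):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}
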