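# -- GenBank flat files, FASTA, registries, design configs -------------------
#
# The GenBank writer/reader implements a small documented dialect: topology is
# taken from the LOCUS line, features are misc_feature entries with /label and
# /note="role=..." qualifiers (origin-wrapping intervals as join(a..L,1..b),
# minus strand as complement(...)), and -- since the flat-file standard has no
# overhang field -- the sticky ends of linear molecules are serialised in a
# structured COMMENT line `ptgr_ends left=<kind>:<overhang>:<enzyme> right=...`.

.fmt_end <- function(e) {
  if (is.null(e)) return("blunt::")
  sprintf("%s:%s:%s", e$kind, e$overhang, if (is.na(e$enzyme)) "" else e$enzyme)
}

.parse_end <- function(txt) {
  bits <- strsplit(txt, ":", fixed = TRUE)[[1L]]
  bits <- c(bits, rep("", 3L - length(bits)))
  sticky_end(bits[1L], bits[2L],
             if (nzchar(bits[3L])) bits[3L] else NA_character_)
}

#' Write a molecule as a GenBank flat file
#'
#' @param m A [dna()] molecule.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_genbank <- function(m, path) {
  stopifnot(inherits(m, "dna"))
  L <- nchar(m$seq)
  name <- if (is.null(m$id)) "molecule" else gsub("[^A-Za-z0-9_.-]", "_", m$id)
  lines <- sprintf("LOCUS       %-16s %d bp    DNA     %-8s SYN 01-JAN-2000",
                   name, L, m$topology)
  lines <- c(lines, "DEFINITION  .")
  if (m$topology == "linear")
    lines <- c(lines, sprintf("COMMENT     ptgr_ends left=%s right=%s",
                              .fmt_end(m$left_end), .fmt_end(m$right_end)))
  lines <- c(lines, "FEATURES             Location/Qualifiers")
  ft <- m$features
  for (i in seq_len(nrow(ft))) {
    s <- ft$start[i]; e <- ft$end[i]
    loc <- if (e <= L) sprintf("%d..%d", s + 1L, e)
           else sprintf("join(%d..%d,1..%d)", s + 1L, L, e - L)
    if (ft$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    lines <- c(lines,
               sprintf("     misc_feature    %s", loc),
               sprintf("                     /label=\"%s\"", ft$label[i]),
               sprintf("                     /note=\"role=%s\"", ft$role[i]))
  }
  lines <- c(lines, "ORIGIN")
  starts <- seq(1L, L, 60L)
  for (s in starts) {
    chunk <- substr(m$seq, s, min(s + 59L, L))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", s, tolower(paste(blocks, collapse = " "))))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

#' Read a molecule from a GenBank flat file
#'
#' Understands the dialect written by [write_genbank()] (see there). Malformed
#' records raise a parse error carrying the offending line number.
#'
#' @param path Input file.
#' @return A [dna()] molecule.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty GenBank file: ", path, call. = FALSE)
  perr <- function(i, msg) stop(sprintf("GenBank parse error at line %d: %s", i, msg),
                                call. = FALSE)
  iloc <- grep("^LOCUS", lines)
  if (!length(iloc)) perr(1L, "no LOCUS line")
  toks <- strsplit(trimws(lines[iloc[1L]]), "[[:space:]]+")[[1L]]
  if (length(toks) < 3L) perr(iloc[1L], "malformed LOCUS line")
  name <- toks[2L]
  topology <- if (any(toks == "circular")) "circular"
              else if (any(toks == "linear")) "linear"
              else perr(iloc[1L], "LOCUS line lacks a topology field")
  left <- .blunt(); right <- .blunt()
  icom <- grep("ptgr_ends", lines)
  if (length(icom)) {
    mm <- regmatches(lines[icom[1L]],
                     regexec("left=([^ ]*) +right=([^ ]*)", lines[icom[1L]]))[[1L]]
    if (length(mm) != 3L) perr(icom[1L], "malformed ptgr_ends comment")
    left <- .parse_end(mm[2L]); right <- .parse_end(mm[3L])
  }
  # features
  ft <- empty_features()
  ifeat <- grep("^     misc_feature", lines)
  for (i in ifeat) {
    loc <- trimws(sub("^     misc_feature", "", lines[i]))
    strand <- "+"
    if (startsWith(loc, "complement(")) {
      strand <- "-"
      loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    }
    if (startsWith(loc, "join(")) {
      parts <- strsplit(sub("^join\\((.*)\\)$", "\\1", loc), ",", fixed = TRUE)[[1L]]
      rng1 <- as.integer(strsplit(parts[1L], "..", fixed = TRUE)[[1L]])
      rng2 <- as.integer(strsplit(parts[2L], "..", fixed = TRUE)[[1L]])
      if (anyNA(c(rng1, rng2))) perr(i, "malformed join location")
      start <- rng1[1L] - 1L
      end <- rng1[2L] + rng2[2L] # wraps: end beyond L
    } else {
      rng <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1L]])
      if (length(rng) != 2L || anyNA(rng)) perr(i, paste("malformed location:", loc))
      start <- rng[1L] - 1L; end <- rng[2L]
    }
    lab <- NA_character_; role <- "misc"
    j <- i + 1L
    while (j <= length(lines) && grepl("^                     /", lines[j])) {
      q <- trimws(lines[j])
      if (startsWith(q, "/label=")) lab <- gsub("\"", "", sub("/label=", "", q))
      if (startsWith(q, "/note=\"role=")) role <- sub("\"$", "", sub("/note=\"role=", "", q))
      j <- j + 1L
    }
    if (is.na(lab)) perr(i, "feature without /label")
    ft <- rbind(ft, features(lab, role, start, end, strand))
  }
  iori <- grep("^ORIGIN", lines)
  if (!length(iori)) perr(length(lines), "no ORIGIN section")
  iend <- grep("^//", lines)
  iend <- iend[iend > iori[1L]][1L]
  if (is.na(iend)) perr(length(lines), "record not terminated with //")
  seqlines <- lines[(iori[1L] + 1L):(iend - 1L)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seqlines, collapse = "")))
  if (!nzchar(seq)) perr(iori[1L], "empty sequence")
  dna(seq, topology, ft, left_end = left, right_end = right, id = name)
}

# -- FASTA --------------------------------------------------------------------

#' Read sequences from a FASTA file
#' @param path FASTA file.
#' @param type "DNA" or "AA".
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  set <- if (type == "DNA") Biostrings::readDNAStringSet(path)
         else Biostrings::readAAStringSet(path)
  stats::setNames(as.character(set), names(set))
}

#' Write named sequences to a FASTA file
#' @param x Named character vector.
#' @param path Output file.
#' @param type "DNA" or "AA".
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(x, path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  set <- if (type == "DNA") Biostrings::DNAStringSet(x) else Biostrings::AAStringSet(x)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# -- part registries ----------------------------------------------------------

.registry_key <- function(role, id) paste0(role, ":", id)

.new_registry <- function(parts) {
  names(parts) <- vapply(parts, function(p) .registry_key(p$role, p$id),
                         character(1L))
  structure(list(parts = parts), class = "part_registry")
}

#' @export
print.part_registry <- function(x, ...) {
  roles <- vapply(x$parts, function(p) p$role, character(1L))
  cat(sprintf("<part registry: %d part(s)>\n", length(x$parts)))
  for (r in unique(roles))
    cat(sprintf("  %-10s %s\n", r,
                paste(vapply(x$parts[roles == r], function(p) p$id, character(1L)),
                      collapse = ", ")))
  invisible(x)
}

#' Fetch a part from a registry
#' @param reg A `part_registry`.
#' @param id Part id.
#' @param role Part role (ids are unique only within a role; e.g. `sod` names
#'   both a promoter and an RBS).
#' @return A [part()].
#' @export
registry_get <- function(reg, id, role) {
  stopifnot(inherits(reg, "part_registry"))
  key <- .registry_key(role, id)
  p <- reg$parts[[key]]
  if (is.null(p)) stop(sprintf("no %s part '%s' in registry", role, id),
                       call. = FALSE)
  p
}

#' Load a part registry from JSON
#'
#' Schema: `{"parts": [{"id", "role", "core_seq", "meta": {...}}, ...]}` with
#' optional meta fields strength_rank, copy_lo, copy_hi, brightness,
#' native_spacing, inducible. Roles and sequences are validated on load.
#'
#' @param path JSON file.
#' @return A `part_registry`.
#' @export
load_registry <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$parts) || !length(obj$parts))
    stop("registry must contain a non-empty 'parts' array", call. = FALSE)
  parts <- lapply(obj$parts, function(rec) {
    for (f in c("id", "role", "core_seq"))
      if (is.null(rec[[f]])) stop("registry part missing field: ", f, call. = FALSE)
    meta <- rec$meta
    part(rec$id, rec$role, rec$core_seq,
         meta = if (is.null(meta)) list() else meta)
  })
  .new_registry(parts)
}

#' Write a part registry to JSON
#' @param reg A `part_registry`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_registry <- function(reg, path) {
  stopifnot(inherits(reg, "part_registry"))
  recs <- lapply(unname(reg$parts), function(p) {
    out <- list(id = p$id, role = p$role, core_seq = p$core_seq)
    meta <- p$meta[!vapply(p$meta, function(v) is.null(v) ||
                             (length(v) == 1L && is.na(v)), logical(1L))]
    meta$id <- NULL; meta$kind <- NULL
    if (length(meta)) out$meta <- meta
    out
  })
  jsonlite::write_json(list(parts = recs), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# -- design specifications ----------------------------------------------------

#' Construct a multi-gene design specification
#'
#' A design is an ordered list of transcriptional units, each an ordered list
#' of genes with their RBS choices; the first gene of a TU carries the TU's
#' promoter. Operons are TUs with more than one gene; clusters are designs
#' with more than one TU.
#'
#' @param tus List of TUs; each TU is
#'   `list(promoter = <id or NA>, genes = list(list(orf = <id>, rbs = <id or NA>), ...))`.
#' @param replicon Host replicon part id.
#' @param name Design/construct name.
#' @return Object of class `ptgr_design`.
#' @export
ptgr_design <- function(tus, replicon = "pGA1", name = "construct") {
  if (!length(tus)) stop("a design needs at least one transcriptional unit",
                         call. = FALSE)
  tus <- lapply(tus, function(tu) {
    if (is.null(tu$genes) || !length(tu$genes))
      stop("every transcriptional unit needs at least one gene", call. = FALSE)
    if (is.null(tu$promoter)) tu$promoter <- NA_character_
    tu$genes <- lapply(tu$genes, function(g) {
      if (is.null(g$orf)) stop("every gene needs an 'orf' id", call. = FALSE)
      if (is.null(g$rbs)) g$rbs <- NA_character_
      g
    })
    tu
  })
  structure(list(name = name, replicon = replicon, tus = tus),
            class = "ptgr_design")
}

#' Read a design specification from YAML or JSON
#'
#' Expected shape:
#' ```yaml
#' name: my_construct
#' replicon: pGA1
#' tus:
#'   - promoter: tac
#'     genes:
#'       - {orf: eGFP, rbs: sod}
#'       - {orf: mCherry, rbs: sod}
#' ```
#'
#' @param path `.yml`/`.yaml` or `.json` file.
#' @return A [ptgr_design()].
#' @export
read_design <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  ptgr_design(obj$tus,
              replicon = if (is.null(obj$replicon)) "pGA1" else obj$replicon,
              name = if (is.null(obj$name)) "construct" else obj$name)
}

#' @export
print.ptgr_design <- function(x, ...) {
  cat(sprintf("<design '%s' on %s: %d TU(s), %d gene(s)>\n", x$name, x$replicon,
              length(x$tus), sum(vapply(x$tus, function(t) length(t$genes), 1L))))
  for (i in seq_along(x$tus)) {
    tu <- x$tus[[i]]
    genes <- vapply(tu$genes, function(g)
      sprintf("%s(rbs=%s)", g$orf, ifelse(is.na(g$rbs), "-", g$rbs)), character(1L))
    cat(sprintf("  TU%d promoter=%s: %s\n", i,
                ifelse(is.na(tu$promoter), "-", tu$promoter),
                paste(genes, collapse = " -> ")))
  }
  invisible(x)
}
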