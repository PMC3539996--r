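# -- one-step gene design: reverse translation + forbidden-site removal ------

#' Load a codon-usage table
#'
#' Structured text with columns `aa` (one-letter amino acid, `*` for stop),
#' `codon` and `freq`. Frequencies must sum to 1 (within 1e-6) for every
#' amino acid, and every standard amino acid plus stop must be present.
#'
#' @param path Tab-separated file.
#' @return Object of class `codon_table`: data frame ordered by aa then
#'   descending frequency.
#' @export
load_codon_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "numeric"))
  if (!all(c("aa", "codon", "freq") %in% names(tab)))
    stop("codon table must have columns aa, codon, freq", call. = FALSE)
  .as_codon_table(tab)
}

.as_codon_table <- function(tab) {
  tab$codon <- toupper(tab$codon)
  gc <- .genetic_code()
  if (!setequal(unique(tab$aa), unique(gc)))
    stop("codon table must cover every standard amino acid and stop", call. = FALSE)
  wrong <- gc[tab$codon] != tab$aa
  if (any(is.na(wrong)) || any(wrong))
    stop("codon table assigns a codon to the wrong amino acid", call. = FALSE)
  sums <- tapply(tab$freq, tab$aa, sum)
  off <- abs(sums - 1) > 1e-6
  if (any(off))
    stop("codon frequencies must sum to 1 per amino acid; off for: ",
         paste(names(sums)[off], collapse = ", "), call. = FALSE)
  tab <- tab[order(tab$aa, -tab$freq, tab$codon), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("codon_table", "data.frame"))
}

.genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

#' The bundled default codon-usage table
#'
#' A synthetic *C. glutamicum*-style table (GC-rich third-position bias),
#' shipped as fixture data; substitute a real organism table for production
#' gene design.
#'
#' @return A `codon_table`.
#' @export
default_codon_table <- function() {
  if (!is.null(.pkg_cache$codon_table)) return(.pkg_cache$codon_table)
  tab <- load_codon_table(system.file("extdata", "codon_usage_cglutamicum_synthetic.tsv",
                                      package = "ptgr"))
  .pkg_cache$codon_table <- tab
  tab
}

# synonyms of `aa`, descending usage
.codons_for <- function(table, aa) table[table$aa == aa, , drop = FALSE]

#' Translate an in-frame DNA sequence
#' @param dna Coding sequence, length divisible by 3.
#' @return Amino-acid string (stop as `*`).
#' @export
translate_dna <- function(dna) {
  .check_seq(dna)
  n <- nchar(dna)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3", call. = FALSE)
  codons <- substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
  paste(.genetic_code()[codons], collapse = "")
}

#' Deterministic reverse translation
#'
#' Greedy choice of the most frequent codon per residue, with the table's
#' preferred stop codon appended.
#'
#' @param protein Amino-acid string (one-letter codes, no stop).
#' @param table A `codon_table` (default: [default_codon_table()]).
#' @return Coding DNA of length `3 * (nchar(protein) + 1)`.
#' @export
reverse_translate <- function(protein, table = default_codon_table()) {
  if (!is.character(protein) || length(protein) != 1L || !nzchar(protein))
    stop("protein must be a non-empty string", call. = FALSE)
  protein <- toupper(protein)
  aas <- strsplit(protein, "", fixed = TRUE)[[1L]]
  valid <- setdiff(unique(.genetic_code()), "*")
  bad <- which(!aas %in% valid)
  if (length(bad))
    stop(sprintf("unknown residue '%s' at position %d", aas[bad[1L]], bad[1L]),
         call. = FALSE)
  pick <- vapply(c(aas, "*"), function(a) .codons_for(table, a)$codon[1L],
                 character(1L), USE.NAMES = FALSE)
  paste(pick, collapse = "")
}

# count forbidden-site occurrences in `padded`, excluding whitelisted
# (position, enzyme) pairs that the slot flanks intend to create
.forbidden_count <- function(padded, recs, whitelist = NULL) {
  total <- 0L
  for (nm in names(recs)) {
    pos <- .scan_seq(padded, recs[[nm]])
    if (!is.null(whitelist[[nm]])) pos <- setdiff(pos, whitelist[[nm]])
    total <- total + length(pos)
  }
  total
}

.first_violation <- function(padded, recs, whitelist = NULL) {
  best <- NULL
  for (nm in names(recs)) {
    pos <- .scan_seq(padded, recs[[nm]])
    if (!is.null(whitelist[[nm]])) pos <- setdiff(pos, whitelist[[nm]])
    if (length(pos) && (is.null(best) || pos[1L] < best$pos))
      best <- list(enzyme = nm, pos = pos[1L], len = nchar(recs[[nm]]))
  }
  best
}

# synonymous repair engine over `dna` embedded as left|dna|right; repairs
# scan left to right, candidate codons overlapping the violating site are
# tried in descending usage, the first strict reduction in total forbidden
# occurrences wins
.scrub_coding <- function(dna, table, forbidden, left = "", right = "",
                          whitelist = NULL) {
  recs <- vapply(forbidden, function(n) enz(n)$recognition, character(1L))
  names(recs) <- forbidden
  ncod <- nchar(dna) %/% 3L
  guard <- 0L
  repeat {
    padded <- paste0(left, dna, right)
    hit <- .first_violation(padded, recs, whitelist)
    if (is.null(hit)) return(dna)
    guard <- guard + 1L
    if (guard > .forbidden_count(paste0(left, dna, right), recs, whitelist) + 10L * ncod)
      stop("forbidden-site removal did not converge", call. = FALSE)
    count0 <- .forbidden_count(padded, recs, whitelist)
    # codons of `dna` overlapping the site (site coords are in padded space)
    s <- hit$pos - nchar(left)
    e <- s + hit$len
    ci <- max(0L, floor(s / 3)):min(ncod - 1L, floor((e - 1L) / 3))
    ci <- ci[ci >= 0L & ci < ncod]
    fixed <- FALSE
    for (k in ci) {
      cur <- .substr0(dna, 3L * k, 3L * k + 3L)
      aa <- .genetic_code()[[cur]]
      alts <- .codons_for(table, aa)$codon
      alts <- alts[alts != cur]
      for (alt in alts) {
        trial <- paste0(.substr0(dna, 0L, 3L * k), alt,
                        .substr0(dna, 3L * k + 3L, nchar(dna)))
        if (.forbidden_count(paste0(left, trial, right), recs, whitelist) < count0) {
          dna <- trial
          fixed <- TRUE
          break
        }
      }
      if (fixed) break
    }
    if (!fixed)
      stop(sprintf("%s site at position %d cannot be removed by synonymous substitution",
                   hit$enzyme, max(s, 0L)), call. = FALSE)
  }
}

#' Remove forbidden restriction sites by synonymous recoding
#'
#' Recodes an in-frame coding sequence so that no forbidden recognition
#' sequence occurs, changing only synonymous codons (translation-invariant).
#' For each violating site (left to right), the codons overlapping it are
#' tried in descending usage order and the first substitution that reduces
#' the number of forbidden occurrences wins, so the procedure is
#' deterministic and terminates. The default forbidden set is the six
#' cassette enzymes every gene entering the standard must avoid.
#'
#' @param dna In-frame coding sequence.
#' @param table A `codon_table`.
#' @param forbidden Enzyme names to exclude.
#' @return Recoded sequence, unchanged if already clean.
#' @export
remove_forbidden_sites <- function(dna, table = default_codon_table(),
                                   forbidden = cassette_enzymes()) {
  .check_seq(dna)
  if (nchar(dna) %% 3L != 0L)
    stop("sequence must be in frame (length divisible by 3)", call. = FALSE)
  .scrub_coding(dna, table, forbidden)
}

#' One-step gene design for the pTGR standard
#'
#' Composes [reverse_translate()] and [remove_forbidden_sites()], additionally
#' scrubbing the flank junction contexts: the CAT the NdeI flank prepends
#' (only the intended CATATG at the start may remain) and the downstream
#' GAATTC of the EcoRI flank (only the intended site at the stop-codon
#' boundary may remain). The result is an ORF [part()] that passes
#' [validate_part()].
#'
#' @param protein Amino-acid sequence; must begin with Met.
#' @param table A `codon_table`.
#' @param forbidden Enzyme names to exclude (default: the six cassette sites).
#' @param id Part id.
#' @return An ORF `ptgr_part`.
#' @export
design_orf <- function(protein, table = default_codon_table(),
                       forbidden = cassette_enzymes(), id = "orf") {
  if (!is.character(protein) || length(protein) != 1L || !nzchar(protein))
    stop("protein must be a non-empty string", call. = FALSE)
  if (toupper(substr(protein, 1L, 1L)) != "M")
    stop("an ORF must begin with Met (the NdeI flank embeds its ATG)",
         call. = FALSE)
  core <- reverse_translate(protein, table)
  whitelist <- list(NdeI = 0L, EcoRI = 3L + nchar(core))
  whitelist <- whitelist[names(whitelist) %in% forbidden]
  core <- .scrub_coding(core, table, forbidden,
                        left = "CAT", right = "GAATTC", whitelist = whitelist)
  p <- part(id, "orf", core, meta = list())
  rep <- validate_part(p)
  if (!report_ok(rep, errors_only = TRUE))
    stop("designed ORF fails validation (should not happen)", call. = FALSE)
  p
}
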