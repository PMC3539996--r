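# -- sequence primitives ------------------------------------------------------

.check_seq <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single character string", call. = FALSE)
  if (!nzchar(seq))
    stop(what, " must be non-empty", call. = FALSE)
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0L)
    stop(sprintf("invalid character '%s' in %s at position %d (alphabet is A/C/G/T)",
                 substr(seq, bad, bad), what, bad), call. = FALSE)
  invisible(seq)
}

#' Reverse complement of a DNA sequence
#'
#' Watson-Crick reverse complement over the strict A/C/G/T alphabet.
#' Ambiguity codes are rejected with the position of the offending character.
#'
#' @param seq Single string over A/C/G/T (top strand, 5'->3').
#' @return The reverse complement, 5'->3'.
#' @examples
#' revcomp("GAATTC")  # palindrome: "GAATTC"
#' @export
revcomp <- function(seq) {
  .check_seq(seq)
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# 0-based half-open substring; `start` may exceed nchar for circular use via %%
.substr0 <- function(seq, start, end) substr(seq, start + 1L, end)

# circular 0-based substring of length `len` starting at `start` (mod L)
.substr_circ <- function(seq, start, len) {
  L <- nchar(seq)
  start <- ((start %% L) + L) %% L
  if (len <= 0L) return("")
  if (start + len <= L) return(.substr0(seq, start, start + len))
  paste0(.substr0(seq, start, L), .substr0(seq, 0L, start + len - L))
}

# -- canonical rotation (Booth's least-rotation algorithm) --------------------

.least_rotation <- function(seq) {
  v <- utf8ToInt(seq)
  n <- length(v)
  if (n == 1L) return(seq)
  S <- c(v, v)
  f <- rep.int(-1L, 2L * n)
  k <- 0L # 0-based index of least rotation
  for (j in 1L:(2L * n - 1L)) {
    sj <- S[j + 1L]
    i <- f[j - k] # f[(j - k - 1) + 1]
    while (i != -1L && sj != S[k + i + 2L]) {
      if (sj < S[k + i + 2L]) k <- j - i - 1L
      i <- f[i + 1L]
    }
    if (sj != S[k + i + 2L]) {
      if (sj < S[k + 1L]) k <- j
      f[j - k + 1L] <- -1L
    } else {
      f[j - k + 1L] <- i + 1L
    }
  }
  .substr_circ(seq, k, n)
}

#' Canonical rotation of a circular sequence
#'
#' Rotation- and strand-invariant identity for plasmids: the lexicographically
#' minimal rotation of the top strand and of its reverse complement, whichever
#' is smaller. Two circular molecules represent the same plasmid iff their
#' canonical rotations are equal.
#'
#' @param x A circular [dna()] molecule or a plain sequence string.
#' @return Single canonical string.
#' @export
canonical_rotation <- function(x) {
  seq <- if (inherits(x, "dna")) x$seq else x
  .check_seq(seq)
  fwd <- .least_rotation(seq)
  rev <- .least_rotation(revcomp(seq))
  if (fwd <= rev) fwd else rev
}

#' Test circular-sequence identity under canonical rotation
#' @param a,b Circular molecules or sequence strings.
#' @return Logical.
#' @export
same_plasmid <- function(a, b) canonical_rotation(a) == canonical_rotation(b)

# -- sticky ends --------------------------------------------------------------

#' Construct a sticky (or blunt) end
#'
#' `overhang` is given 5'->3' on the protruding strand. The `enzyme` field
#' records which enzyme generated the end; it is used to reconstruct junction
#' scars after ligation.
#'
#' @param kind One of "blunt", "five_prime", "three_prime".
#' @param overhang Protruding single-strand sequence (empty iff blunt).
#' @param enzyme Optional generating enzyme name.
#' @return Object of class `sticky_end`.
#' @export
sticky_end <- function(kind = c("blunt", "five_prime", "three_prime"),
                       overhang = "", enzyme = NA_character_) {
  kind <- match.arg(kind)
  if (kind == "blunt") {
    if (nzchar(overhang)) stop("blunt ends carry no overhang", call. = FALSE)
  } else {
    .check_seq(overhang, "overhang")
  }
  structure(list(kind = kind, overhang = overhang, enzyme = enzyme),
            class = "sticky_end")
}

#' @export
print.sticky_end <- function(x, ...) {
  if (x$kind == "blunt") cat("<blunt end>\n")
  else cat(sprintf("<%s overhang %s%s>\n", sub("_", "-", x$kind), x$overhang,
                   if (!is.na(x$enzyme)) paste0(" [", x$enzyme, "]") else ""))
  invisible(x)
}

.blunt <- function() sticky_end("blunt")

# -- feature table ------------------------------------------------------------

#' Empty feature table
#'
#' Features are 0-based half-open intervals on the top strand. On circular
#' molecules a feature may wrap the origin, encoded as `end > L` (interval
#' `[start, start + width)` with positions taken mod L).
#'
#' @return Zero-row feature data frame.
#' @export
empty_features <- function() {
  data.frame(label = character(), role = character(),
             start = integer(), end = integer(), strand = character(),
             stringsAsFactors = FALSE)
}

#' Build a feature table
#' @param label,role,start,end,strand Vectors of equal length.
#' @export
features <- function(label, role, start, end, strand = "+") {
  data.frame(label = as.character(label), role = as.character(role),
             start = as.integer(start), end = as.integer(end),
             strand = rep_len(as.character(strand), length(label)),
             stringsAsFactors = FALSE)
}

.check_features <- function(ft, L, circular) {
  if (nrow(ft) == 0L) return(invisible(ft))
  if (any(ft$end - ft$start < 1L))
    stop("feature intervals must have length >= 1", call. = FALSE)
  if (any(ft$start < 0L) || any(ft$start >= L))
    stop("feature start out of range [0, length)", call. = FALSE)
  if (!circular && any(ft$end > L))
    stop("feature beyond the end of a linear molecule", call. = FALSE)
  if (circular && any(ft$end > ft$start + L))
    stop("feature longer than the circular molecule", call. = FALSE)
  if (!all(ft$strand %in% c("+", "-")))
    stop("feature strand must be '+' or '-'", call. = FALSE)
  named <- ft$label[ft$role != "site"]
  if (anyDuplicated(named))
    stop("duplicate feature label: ", named[duplicated(named)][1L], call. = FALSE)
  invisible(ft)
}

# -- the molecule -------------------------------------------------------------

#' Annotated double-stranded DNA molecule
#'
#' The core container of the simulator: a top-strand sequence (5'->3') with
#' topology, an ordered feature table and, for linear molecules, two sticky
#' ends. By convention the stored top strand *includes* a 5' overhang at the
#' left end and a 3' overhang at the right end (their complements live on the
#' bottom strand of the neighbouring fragment), so top-strand lengths are
#' conserved under digestion.
#'
#' @param seq Top strand over A/C/G/T.
#' @param topology "linear" or "circular".
#' @param features Feature table, see [features()].
#' @param left_end,right_end [sticky_end()]s; linear molecules only.
#' @param id Optional identifier.
#' @return Object of class `dna`.
#' @export
dna <- function(seq, topology = c("linear", "circular"),
                features = empty_features(),
                left_end = .blunt(), right_end = .blunt(), id = NULL) {
  topology <- match.arg(topology)
  .check_seq(seq)
  circular <- topology == "circular"
  if (circular && (!identical(left_end$kind, "blunt") ||
                   !identical(right_end$kind, "blunt")))
    stop("circular molecules carry no ends", call. = FALSE)
  stopifnot(inherits(left_end, "sticky_end"), inherits(right_end, "sticky_end"))
  .check_features(features, nchar(seq), circular)
  structure(list(seq = seq, topology = topology, features = features,
                 left_end = if (circular) NULL else left_end,
                 right_end = if (circular) NULL else right_end,
                 id = id),
            class = "dna")
}

#' @export
print.dna <- function(x, ...) {
  L <- nchar(x$seq)
  cat(sprintf("<dna %s: %d bp%s>\n", x$topology, L,
              if (!is.null(x$id)) paste0(" '", x$id, "'") else ""))
  if (x$topology == "linear") {
    cat("  left : "); print(x$left_end)
    cat("  right: "); print(x$right_end)
  }
  ft <- x$features
  if (nrow(ft)) {
    show <- utils::head(ft, 20L)
    for (i in seq_len(nrow(show)))
      cat(sprintf("  %-14s %-10s %6d..%-6d %s\n", show$label[i], show$role[i],
                  show$start[i], show$end[i], show$strand[i]))
    if (nrow(ft) > 20L) cat("  ... and", nrow(ft) - 20L, "more features\n")
  }
  invisible(x)
}

#' @export
length.dna <- function(x) nchar(x$seq)

.is_circular <- function(m) m$topology == "circular"

#' Reverse-complement a molecule
#'
#' Flips a molecule onto its other strand. Feature coordinates and strands are
#' transformed; for linear fragments the sticky ends swap sides (the stored
#' overhang text, being written on the protruding strand, is unchanged), and
#' the new top strand is the old bottom strand read 5'->3', which can differ
#' in length from the old top strand when the two overhangs differ in length.
#'
#' @param m A [dna()] molecule.
#' @return The flipped molecule.
#' @export
revcomp_molecule <- function(m) {
  stopifnot(inherits(m, "dna"))
  if (.is_circular(m)) {
    L <- nchar(m$seq)
    ft <- m$features
    if (nrow(ft)) {
      s <- ft$start %% L
      e <- ft$end
      ns <- (L - e) %% L
      ft$start <- as.integer(ns)
      ft$end <- as.integer(ns + (e - s))
      ft$strand <- ifelse(ft$strand == "+", "-", "+")
      ft <- ft[order(ft$start, ft$end), , drop = FALSE]
      rownames(ft) <- NULL
    }
    return(dna(revcomp(m$seq), "circular", ft, id = m$id))
  }
  le <- m$left_end; re <- m$right_end
  l5 <- le$kind == "five_prime";  l3 <- le$kind == "three_prime"
  r5 <- re$kind == "five_prime";  r3 <- re$kind == "three_prime"
  # E: full column extent on the top-strand sense
  E <- paste0(if (l3) revcomp(le$overhang) else "",
              m$seq,
              if (r5) revcomp(re$overhang) else "")
  bstart <- if (l5) nchar(le$overhang) else 0L      # bottom-strand extent in E
  bend <- nchar(E) - if (r3) nchar(re$overhang) else 0L
  newtop <- revcomp(.substr0(E, bstart, bend))
  toff <- if (l3) nchar(le$overhang) else 0L        # old top offset within E
  ft <- m$features
  if (nrow(ft)) {
    sE <- ft$start + toff
    eE <- ft$end + toff
    ns <- bend - eE
    ne <- bend - sE
    keep <- pmax(ns, 0L) < pmin(ne, nchar(newtop))
    ft <- ft[keep, , drop = FALSE]
    if (nrow(ft)) {
      ft$start <- as.integer(pmax(ns[keep], 0L))
      ft$end <- as.integer(pmin(ne[keep], nchar(newtop)))
      ft$strand <- ifelse(ft$strand == "+", "-", "+")
      ft <- ft[order(ft$start, ft$end), , drop = FALSE]
      rownames(ft) <- NULL
    }
  }
  dna(newtop, "linear", ft, left_end = re, right_end = le, id = m$id)
}

# shift features by `off` and keep bookkeeping tidy
.shift_features <- function(ft, off) {
  if (nrow(ft) == 0L) return(ft)
  ft$start <- as.integer(ft$start + off)
  ft$end <- as.integer(ft$end + off)
  ft
}
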