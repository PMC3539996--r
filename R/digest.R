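# -- site scanning and complete digestion ------------------------------------

#' Scan a molecule for an enzyme's recognition sites
#'
#' All occurrences of the recognition sequence on the top strand, 0-based.
#' Circular molecules include origin-spanning occurrences, reported mod the
#' sequence length. All shipped enzymes are palindromic, so the top-strand
#' scan is complete; non-palindromic enzymes would require scanning both
#' strands.
#'
#' @param m A [dna()] molecule.
#' @param e An enzyme (object or name).
#' @return Ordered integer vector of 0-based site start positions.
#' @export
scan_sites <- function(m, e) {
  stopifnot(inherits(m, "dna"))
  e <- .as_enzyme(e)
  .scan_seq(m$seq, e$recognition, circular = .is_circular(m))
}

.scan_seq <- function(seq, pattern, circular = FALSE) {
  L <- nchar(seq)
  k <- nchar(pattern)
  subject <- if (circular && L >= k) paste0(seq, .substr0(seq, 0L, k - 1L)) else seq
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer())
  pos <- as.integer(hits) - 1L
  sort(unique(pos[pos < L]))
}

# count occurrences of each shipped site on a molecule
.site_census <- function(m, which = names(enzymes())) {
  vapply(which, function(n) length(scan_sites(m, n)), integer(1L))
}

#' Re-derive "site" features from the sequence
#'
#' Drops existing `role == "site"` features and annotates every occurrence of
#' every shipped recognition site.
#'
#' @param m A [dna()] molecule.
#' @return The molecule with refreshed site features.
#' @export
annotate_sites <- function(m) {
  ft <- m$features[m$features$role != "site", , drop = FALSE]
  for (e in enzymes()) {
    pos <- scan_sites(m, e)
    if (length(pos))
      ft <- rbind(ft, features(rep(e$name, length(pos)), "site",
                               pos, pos + nchar(e$recognition)))
  }
  ft <- ft[order(ft$start, ft$end), , drop = FALSE]
  rownames(ft) <- NULL
  m$features <- ft
  m
}

#' Was a digestion a no-op on a circular molecule?
#' @param frags Result of [digest()].
#' @return Logical.
#' @export
is_uncut <- function(frags) isTRUE(attr(frags, "uncut"))

#' Simulate complete digestion
#'
#' Cuts a molecule with one or more enzymes, assuming complete digestion. A
#' circular molecule with k cut positions yields exactly k linear fragments; a
#' linear one yields k+1. Each fragment carries sticky ends derived from the
#' cutting enzyme's offsets, sliced and re-anchored features, and provenance
#' (source id, cut coordinates) as an attribute. Truncated `"site"` features
#' are dropped (they can be re-derived with [annotate_sites()]).
#'
#' A circular molecule with no sites returns an empty list flagged with the
#' `uncut` attribute (see [is_uncut()]) -- a signal distinct from an error.
#' Cut sites closer together than the overhang they produce raise a
#' site-collision error.
#'
#' @param m A [dna()] molecule.
#' @param enzymes_used Enzyme, enzyme name, or list of them.
#' @return List of linear [dna()] fragments.
#' @export
digest <- function(m, enzymes_used) {
  stopifnot(inherits(m, "dna"))
  if (inherits(enzymes_used, "enzyme") || is.character(enzymes_used))
    enzymes_used <- as.list(enzymes_used)
  if (length(enzymes_used) < 1L) stop("at least one enzyme required", call. = FALSE)
  enzymes_used <- lapply(enzymes_used, .as_enzyme)
  L <- nchar(m$seq)
  circ <- .is_circular(m)

  cuts <- do.call(rbind, lapply(enzymes_used, function(e) {
    sites <- scan_sites(m, e)
    if (!length(sites)) return(NULL)
    data.frame(enzyme = e$name, site = sites,
               t = if (circ) (sites + e$cut_top) %% L else sites + e$cut_top,
               lo = sites + min(e$cut_top, e$cut_bottom),
               hi = sites + max(e$cut_top, e$cut_bottom),
               glen = e$cut_bottom - e$cut_top, # >0: 5' overhang, <0: 3'
               stringsAsFactors = FALSE)
  }))

  if (is.null(cuts) || nrow(cuts) == 0L) {
    if (circ) return(structure(list(), uncut = TRUE))
    return(list(m))
  }

  cuts <- cuts[order(cuts$lo), , drop = FALSE]
  # site-collision audit: overhang arcs must not overlap (cyclically if circular)
  k <- nrow(cuts)
  if (k > 1L || circ) {
    lo <- cuts$lo; hi <- pmax(cuts$hi, cuts$lo + 1L) # blunt cuts occupy a point
    nxt <- c(lo[-1L], if (circ) lo[1L] + L else Inf)
    if (any(hi > nxt))
      stop("site-collision: cut sites closer than the overhang length",
           call. = FALSE)
  }

  cuts <- cuts[order(cuts$t %% max(L, 1L), cuts$lo), , drop = FALSE]
  ends_at_cut <- lapply(seq_len(nrow(cuts)), function(i) .cut_ends(m$seq, cuts[i, ], circ, L))

  frags <- list()
  if (circ) {
    n <- nrow(cuts)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      from <- cuts$t[i]
      len <- if (n == 1L) L else ((cuts$t[j] - cuts$t[i]) %% L)
      if (len == 0L)
        stop("site-collision: two cuts at the same top-strand position",
             call. = FALSE)
      frags[[i]] <- .make_fragment(m, from, len, ends_at_cut[[i]]$right_frag_left,
                                   ends_at_cut[[j]]$left_frag_right, circ, L,
                                   cut_from = cuts[i, ], cut_to = cuts[j, ])
    }
  } else {
    bounds <- c(0L, cuts$t, L)
    n <- nrow(cuts)
    for (i in seq_len(n + 1L)) {
      from <- bounds[i]; len <- bounds[i + 1L] - from
      left <- if (i == 1L) m$left_end else ends_at_cut[[i - 1L]]$right_frag_left
      right <- if (i == n + 1L) m$right_end else ends_at_cut[[i]]$left_frag_right
      frags[[i]] <- .make_fragment(m, from, len, left, right, circ, L,
                                   cut_from = if (i > 1L) cuts[i - 1L, ],
                                   cut_to = if (i <= n) cuts[i, ])
    }
  }
  frags
}

# ends generated by one cut: the left end of the downstream (right) fragment
# and the right end of the upstream (left) fragment
.cut_ends <- function(seq, cut, circ, L) {
  g <- cut$glen
  if (g == 0L) {
    return(list(right_frag_left = sticky_end("blunt", enzyme = cut$enzyme),
                left_frag_right = sticky_end("blunt", enzyme = cut$enzyme)))
  }
  if (g > 0L) { # 5' overhang: gap [t, t+g) protrudes on top of right fragment
    gap <- if (circ) .substr_circ(seq, cut$t, g) else .substr0(seq, cut$t, cut$t + g)
    list(right_frag_left = sticky_end("five_prime", gap, cut$enzyme),
         left_frag_right = sticky_end("five_prime", revcomp(gap), cut$enzyme))
  } else {      # 3' overhang: gap [t+g, t) protrudes on top of left fragment
    gap <- if (circ) .substr_circ(seq, cut$t + g, -g) else .substr0(seq, cut$t + g, cut$t)
    list(right_frag_left = sticky_end("three_prime", revcomp(gap), cut$enzyme),
         left_frag_right = sticky_end("three_prime", gap, cut$enzyme))
  }
}

.make_fragment <- function(m, from, len, left_end, right_end, circ, L,
                           cut_from = NULL, cut_to = NULL) {
  seq <- if (circ) .substr_circ(m$seq, from, len) else .substr0(m$seq, from, from + len)
  if (!nzchar(seq))
    stop("digestion produced an empty fragment (adjacent cut positions)",
         call. = FALSE)
  ft <- .slice_features(m$features, from, len, L, circ)
  frag <- dna(seq, "linear", ft, left_end = left_end, right_end = right_end,
              id = if (!is.null(m$id)) paste0(m$id, ":", from, "+", len))
  attr(frag, "provenance") <- list(source = m$id, from = from, len = len,
                                   cut_from = cut_from$enzyme,
                                   cut_to = cut_to$enzyme)
  frag
}

# slice source features into the window [from, from+len), re-anchored at 0
.slice_features <- function(ft, from, len, L, circ) {
  out <- empty_features()
  if (nrow(ft) == 0L) return(out)
  shifts <- if (circ) c(-L, 0L, L) else 0L
  counter <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(ft))) {
    full <- ft$end[i] - ft$start[i]
    for (d in shifts) {
      s <- ft$start[i] + d; e <- ft$end[i] + d
      ns <- max(s, from); ne <- min(e, from + len)
      if (ne - ns < 1L) next
      lab <- ft$label[i]
      truncated <- (ne - ns) < full
      if (truncated) {
        if (ft$role[i] == "site") next # re-derivable; drop partial sites
        n <- (get0(lab, envir = counter, ifnotfound = 0L)) + 1L
        assign(lab, n, envir = counter)
        lab <- sprintf("%s|part%d", lab, n)
      }
      out <- rbind(out, features(lab, ft$role[i], ns - from, ne - from,
                                 ft$strand[i]))
    }
  }
  if (nrow(out)) {
    out <- out[order(out$start, out$end), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
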