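# -- sticky-end compatibility, junction scars, circular ligation -------------

#' Can two ends be ligated?
#'
#' True iff both ends are blunt, or both carry the same overhang kind and
#' their protruding strands are reverse complements of each other (for the
#' self-complementary CTAG family of the pTGR cassette, this means identical
#' overhangs). `a` is read as the upstream fragment's right end and `b` as
#' the downstream fragment's left end.
#'
#' @param a,b [sticky_end()] objects.
#' @return Logical.
#' @export
ends_compatible <- function(a, b) {
  stopifnot(inherits(a, "sticky_end"), inherits(b, "sticky_end"))
  if (a$kind == "blunt" && b$kind == "blunt") return(TRUE)
  if (a$kind != b$kind) return(FALSE)
  nchar(a$overhang) == nchar(b$overhang) && a$overhang == revcomp(b$overhang)
}

#' Sequence and site content of a ligation junction
#'
#' Reconstructs the duplex across the joint of two compatible enzyme-cut ends
#' and reports which shipped recognition sites span the junction ("regenerated"
#' sites) -- computed by scanning, never asserted. The scar is the retained
#' part of the upstream enzyme's recognition sequence followed by the retained
#' part of the downstream enzyme's, e.g. an AvrII-cut vector end joined to an
#' NheI-cut fragment start gives the dead scar \code{CCTAGC}, while AvrII to
#' AvrII regenerates \code{CCTAGG}.
#'
#' @param upstream_end Right end of the upstream fragment.
#' @param downstream_end Left end of the downstream fragment.
#' @return Object of class `junction`: list with `scar_seq`, `sites_present`
#'   (enzyme names whose site spans the joint), `enzymes` and `joint` (0-based
#'   offset of the joint within `scar_seq`).
#' @export
junction_sequence <- function(upstream_end, downstream_end) {
  if (!ends_compatible(upstream_end, downstream_end))
    stop("incompatible ends cannot be ligated", call. = FALSE)
  up <- upstream_end; dn <- downstream_end
  if (is.na(up$enzyme) || is.na(dn$enzyme)) {
    scar <- if (dn$kind == "five_prime") dn$overhang
            else if (dn$kind == "three_prime") up$overhang else ""
    return(structure(list(scar_seq = scar, sites_present = character(),
                          enzymes = c(up$enzyme, dn$enzyme), joint = 0L),
                     class = "junction"))
  }
  eu <- enz(up$enzyme); ed <- enz(dn$enzyme)
  left <- .substr0(eu$recognition, 0L, eu$cut_top)
  right <- .substr0(ed$recognition, ed$cut_top, nchar(ed$recognition))
  scar <- paste0(left, right)
  joint <- nchar(left)
  present <- vapply(enzymes(), function(e) {
    pos <- .scan_seq(scar, e$recognition)
    any(pos < joint & pos + nchar(e$recognition) > joint)
  }, logical(1L))
  structure(list(scar_seq = scar, sites_present = names(present)[present],
                 enzymes = c(eu$name, ed$name), joint = as.integer(joint)),
            class = "junction")
}

#' @export
print.junction <- function(x, ...) {
  cat(sprintf("<junction %s/%s scar %s%s>\n",
              x$enzymes[1L], x$enzymes[2L], x$scar_seq,
              if (length(x$sites_present))
                paste0(" regenerates ", paste(x$sites_present, collapse = ","))
              else " (dead)"))
  invisible(x)
}

#' Enumerate circular ligation products
#'
#' Self-circularisation for one fragment; for two fragments, both relative
#' orientations wherever the ends permit. Products are deduplicated under
#' canonical rotation (including the reverse-complement strand) and carry a
#' scar feature at every junction, labelled with the two parent enzyme names.
#' No compatible end pairing yields an empty list, not an error. Ligations of
#' more than two fragments are out of scope (the pTGR procedures never need
#' them).
#'
#' @param fragments List of 1 or 2 linear [dna()] fragments (a single
#'   fragment may also be passed bare).
#' @param id Optional id for the products.
#' @return List of distinct circular [dna()] molecules.
#' @export
ligate_circular <- function(fragments, id = NULL) {
  if (inherits(fragments, "dna")) fragments <- list(fragments)
  if (length(fragments) < 1L || length(fragments) > 2L)
    stop("ligate_circular handles 1 or 2 fragments", call. = FALSE)
  for (f in fragments)
    if (!inherits(f, "dna") || .is_circular(f))
      stop("all fragments must be linear dna molecules", call. = FALSE)

  products <- list()
  if (length(fragments) == 1L) {
    f <- fragments[[1L]]
    if (ends_compatible(f$right_end, f$left_end))
      products <- list(.circularise(list(f), id))
  } else {
    a <- fragments[[1L]]
    for (bo in list(fragments[[2L]], revcomp_molecule(fragments[[2L]]))) {
      if (ends_compatible(a$right_end, bo$left_end) &&
          ends_compatible(bo$right_end, a$left_end))
        products <- c(products, list(.circularise(list(a, bo), id)))
    }
  }
  if (length(products) > 1L) {
    keys <- vapply(products, canonical_rotation, character(1L))
    products <- products[!duplicated(keys)]
  }
  products
}

# join fragments head-to-tail into a circle, annotating scars
.circularise <- function(frs, id = NULL) {
  seqs <- vapply(frs, function(f) f$seq, character(1L))
  seq <- paste(seqs, collapse = "")
  L <- nchar(seq)
  offs <- cumsum(c(0L, nchar(seqs)))[seq_along(frs)]
  ft <- empty_features()
  for (i in seq_along(frs)) {
    fi <- frs[[i]]$features
    fi <- fi[fi$role != "site", , drop = FALSE]
    ft <- rbind(ft, .shift_features(fi, offs[i]))
  }
  for (i in seq_along(frs)) {
    up <- frs[[i]]$right_end
    dn <- frs[[if (i == length(frs)) 1L else i + 1L]]$left_end
    jn <- junction_sequence(up, dn)
    if (!nzchar(jn$scar_seq)) next
    # the joint sits at the boundary after fragment i (position `at` mod L)
    at <- if (i == length(frs)) L else offs[i + 1L]
    start <- (at - jn$joint) %% L
    ft <- rbind(ft, features(sprintf("scar:%s/%s", jn$enzymes[1L], jn$enzymes[2L]),
                             "scar", start, start + nchar(jn$scar_seq)))
  }
  # scar features may straddle the origin; dna() permits end > L wraps
  if (nrow(ft)) {
    ft <- ft[order(ft$start, ft$end), , drop = FALSE]
    ft <- .uniquify_labels(ft)
    rownames(ft) <- NULL
  }
  dna(seq, "circular", ft, id = id)
}

# merged feature tables can carry repeated part labels (e.g. the same RBS in
# two transcriptional units); suffix repeats to keep molecule labels unique
.uniquify_labels <- function(ft) {
  nonsite <- ft$role != "site"
  lab <- ft$label[nonsite]
  dup <- duplicated(lab) | duplicated(lab, fromLast = TRUE)
  if (any(dup)) {
    idx <- stats::ave(seq_along(lab), lab, FUN = seq_along)
    lab[dup] <- sprintf("%s#%d", lab[dup], idx[dup])
    ft$label[nonsite] <- lab
  }
  ft
}
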