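# -- type-II restriction enzymes ---------------------------------------------

#' Define a type-II restriction enzyme
#'
#' `cut_top` and `cut_bottom` are offsets from the start of the recognition
#' sequence at which the top and bottom strands are cut (both expressed in
#' top-strand coordinates). `cut_top < cut_bottom` gives a 5' overhang,
#' `cut_top > cut_bottom` a 3' overhang, equality a blunt cut. Only
#' unambiguous recognition sequences are supported; ambiguity codes are
#' rejected.
#'
#' @param name Enzyme name.
#' @param recognition Unambiguous recognition sequence (top strand).
#' @param cut_top,cut_bottom Integer cut offsets.
#' @return Object of class `enzyme`.
#' @export
restriction_enzyme <- function(name, recognition, cut_top, cut_bottom) {
  .check_seq(recognition, paste0("recognition sequence of ", name))
  cut_top <- as.integer(cut_top); cut_bottom <- as.integer(cut_bottom)
  k <- nchar(recognition)
  if (cut_top < 0L || cut_top > k || cut_bottom < 0L || cut_bottom > k)
    stop("cut offsets must lie within the recognition sequence", call. = FALSE)
  structure(list(name = name, recognition = recognition,
                 cut_top = cut_top, cut_bottom = cut_bottom),
            class = "enzyme")
}

#' @export
print.enzyme <- function(x, ...) {
  ov <- enzyme_overhang(x)
  cat(sprintf("<enzyme %s %s^ (%s%s)>\n", x$name, x$recognition,
              sub("_", "-", ov$kind),
              if (nzchar(ov$overhang)) paste0(" ", ov$overhang) else ""))
  invisible(x)
}

#' Overhang generated by an enzyme
#'
#' @param e An [restriction_enzyme()].
#' @return List with `kind` and `overhang` (the protruding strand 5'->3' as it
#'   appears on the left/upstream-facing end of the downstream fragment).
#' @export
enzyme_overhang <- function(e) {
  t <- e$cut_top; b <- e$cut_bottom
  if (t == b) return(list(kind = "blunt", overhang = ""))
  if (t < b)  return(list(kind = "five_prime",
                          overhang = .substr0(e$recognition, t, b)))
  list(kind = "three_prime",
       overhang = .substr0(e$recognition, b, t))
}

.pkg_cache <- new.env(parent = emptyenv())

#' The shipped enzyme registry
#'
#' The eleven enzymes of the pTGR standard (cassette set XbaI, SpeI, NheI,
#' AvrII, NdeI, EcoRI plus backbone set BamHI, BglII, SphI, PstI, KpnI), read
#' from the bundled structured text table. All are palindromic, so a
#' single-strand site scan is complete; non-palindromic extensions would have
#' to scan both strands.
#'
#' @param path Optional path to an alternative tab-separated registry with
#'   columns name, recognition, cut_top, cut_bottom.
#' @return Named list of `enzyme` objects.
#' @export
enzymes <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.pkg_cache$enzymes)) return(.pkg_cache$enzymes)
    path <- system.file("extdata", "enzymes.tsv", package = "ptgr")
    cache <- TRUE
  } else cache <- FALSE
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "recognition", "cut_top", "cut_bottom")
  if (!all(need %in% names(tab)))
    stop("enzyme registry must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i)
    restriction_enzyme(tab$name[i], tab$recognition[i],
                       tab$cut_top[i], tab$cut_bottom[i]))
  names(out) <- tab$name
  if (cache) .pkg_cache$enzymes <- out
  out
}

#' Look up a shipped enzyme by name
#' @param name Enzyme name, e.g. `"NheI"`.
#' @return An `enzyme` object.
#' @export
enz <- function(name) {
  reg <- enzymes()
  if (!name %in% names(reg)) stop("unknown enzyme: ", name, call. = FALSE)
  reg[[name]]
}

#' The six cassette enzymes forbidden inside transcriptional-unit parts
#' @return Character vector of enzyme names.
#' @export
cassette_enzymes <- function() c("NdeI", "EcoRI", "XbaI", "SpeI", "NheI", "AvrII")

# resolve a user-supplied enzyme spec (name or object) to an object
.as_enzyme <- function(e) {
  if (inherits(e, "enzyme")) return(e)
  if (is.character(e) && length(e) == 1L) return(enz(e))
  stop("expected an enzyme or enzyme name", call. = FALSE)
}
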