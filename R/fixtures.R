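# -- deterministic synthetic fixtures ----------------------------------------
#
# The real platform part sequences are not published, so the package ships a
# seeded generator that emits synthetic stand-ins for every part class:
# random site-clean cores of realistic length, RBSs with a planted
# Shine-Dalgarno motif at the declared native spacing, reporter ORFs designed
# through the geneprep pipeline, and the paper-derived strength/copy-number/
# brightness metadata attached. Identical seeds give byte-identical output.

# run code under a seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.random_dna <- function(n, gc = 0.54) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}

# deterministically mutate `core` until no shipped recognition site occurs in
# left|core|right; `protect` is a 0-based interval of core positions never
# touched (e.g. a planted SD motif)
.scrub_random <- function(core, left = "", right = "", protect = c(-1L, -1L)) {
  recs <- vapply(enzymes(), function(e) e$recognition, character(1L))
  nl <- nchar(left)
  # only occurrences overlapping the core count; the pads are the intended
  # flanking sites themselves
  hits1 <- function(s, r, ncore) {
    pos <- .scan_seq(s, r)
    pos[pos + nchar(r) > nl & pos < nl + ncore]
  }
  count <- function(s, ncore)
    sum(vapply(recs, function(r) length(hits1(s, r, ncore)), 1L))
  guard <- 0L
  repeat {
    padded <- paste0(left, core, right)
    n0 <- count(padded, nchar(core))
    if (n0 == 0L) return(core)
    guard <- guard + 1L
    if (guard > 50L * nchar(core))
      stop("fixture scrubbing did not converge", call. = FALSE)
    hit <- NULL
    for (r in recs) {
      pos <- hits1(padded, r, nchar(core))
      if (length(pos) && (is.null(hit) || pos[1L] < hit$pos))
        hit <- list(pos = pos[1L], len = nchar(r))
    }
    # candidate core positions within the site, rightmost first, skipping the
    # protected interval when possible
    cand <- (hit$pos:(hit$pos + hit$len - 1L)) - nchar(left)
    cand <- cand[cand >= 0L & cand < nchar(core)]
    unprot <- cand[cand < protect[1L] | cand >= protect[2L]]
    cand <- rev(if (length(unprot)) unprot else cand)
    done <- FALSE
    for (pos in cand) {
      cur <- .substr0(core, pos, pos + 1L)
      for (b in setdiff(c("A", "C", "G", "T"), cur)) {
        trial <- paste0(.substr0(core, 0L, pos), b,
                        .substr0(core, pos + 1L, nchar(core)))
        if (count(paste0(left, trial, right), nchar(trial)) < n0) {
          core <- trial; done <- TRUE; break
        }
      }
      if (done) break
    }
    if (!done) stop("fixture scrubbing stuck", call. = FALSE)
  }
}

.random_protein <- function(n) {
  aas <- setdiff(unique(.genetic_code()), c("*", "M"))
  paste0("M", paste(sample(aas, n - 1L, replace = TRUE), collapse = ""))
}

# an RBS core of length `len` with AGGAGG planted so the measured SD->ATG
# spacing (through the CAT of the NdeI flank) equals `spacing`
.random_rbs <- function(len, spacing) {
  tail_len <- spacing - 4L
  stopifnot(tail_len >= 0L, len >= tail_len + 6L + 1L)
  head_len <- len - 6L - tail_len
  core <- paste0(.random_dna(head_len), "AGGAGG", .random_dna(tail_len))
  .scrub_random(core, left = "GCTAGC", right = "CATATG",
                protect = c(head_len, head_len + 6L))
}

#' Generate the synthetic fixture part set
#'
#' Emits a site-clean random part for every slot role -- three promoters and
#' three RBSs whose strength ranks mirror the characterised parts, two
#' reporter-ORF stand-ins (eGFP- and mCherry-sized, built with
#' [design_orf()] against all eleven shipped sites), a tandem-terminator
#' stand-in, three host replicons with copy-number metadata, an E. coli
#' origin, a selectable marker and a LacI-type regulator cassette -- plus an
#' assembled promoterless single-TU backbone plasmid carrying the eGFP
#' stand-in.
#'
#' @param seed Integer seed; identical seeds give byte-identical fixtures.
#' @param lengths Named list overriding part core lengths.
#' @return List with `registry` (a `part_registry`) and `backbone` (a
#'   circular [dna()] plasmid).
#' @export
generate_fixtures <- function(seed = 42L,
                              lengths = list(promoter = 200L, rbs = 20L,
                                             terminator = 150L, backbone = 1000L,
                                             egfp_aa = 239L, mcherry_aa = 236L)) {
  .with_seed(seed, {
    all11 <- names(enzymes())
    mk <- function(id, role, len, left, right)
      part(id, role, .scrub_random(.random_dna(len), left, right))
    parts <- list(
      part("tac", "promoter", .scrub_random(.random_dna(lengths$promoter),
                                            "TCTAGA", "GCTAGC")),
      part("cspB", "promoter", .scrub_random(.random_dna(lengths$promoter),
                                             "TCTAGA", "GCTAGC")),
      part("sod", "promoter", .scrub_random(.random_dna(lengths$promoter),
                                            "TCTAGA", "GCTAGC")),
      part("sod", "rbs", .random_rbs(lengths$rbs, 7L)),
      part("lacZ", "rbs", .random_rbs(lengths$rbs, 8L)),
      part("cspB", "rbs", .random_rbs(lengths$rbs, 9L)),
      design_orf(.random_protein(lengths$egfp_aa), forbidden = all11, id = "eGFP"),
      design_orf(.random_protein(lengths$mcherry_aa), forbidden = all11, id = "mCherry"),
      part("rrnBT1T2", "terminator",
           .scrub_random(.random_dna(lengths$terminator), "CCTAGG", "ACTAGT")),
      mk("lacI", "regulator", lengths$backbone, "GGATCC", "AGATCT"),
      mk("ColE1", "ecoli_ori", lengths$backbone, "AGATCT", "GCATGC"),
      mk("kan", "marker", lengths$backbone, "GCATGC", "CTGCAG"),
      mk("pGA1", "host_ori", lengths$backbone, "CTGCAG", "GGTACC"),
      mk("pCRY4", "host_ori", lengths$backbone, "CTGCAG", "GGTACC"),
      mk("pNG2", "host_ori", lengths$backbone, "CTGCAG", "GGTACC"))
    reg <- .new_registry(parts)
    backbone <- assemble_single_tu(
      host_ori = registry_get(reg, "pGA1", "host_ori"),
      ecoli_ori = registry_get(reg, "ColE1", "ecoli_ori"),
      marker = registry_get(reg, "kan", "marker"),
      orf = registry_get(reg, "eGFP", "orf"),
      terminator = registry_get(reg, "rrnBT1T2", "terminator"),
      id = "backbone")
    list(registry = reg, backbone = backbone)
  })
}

#' The cached default fixture registry (seed 42)
#' @return A `part_registry`.
#' @export
default_registry <- function() {
  if (is.null(.pkg_cache$registry))
    .pkg_cache$registry <- generate_fixtures(42L)$registry
  .pkg_cache$registry
}
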