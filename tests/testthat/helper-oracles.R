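# shared fixtures and independent oracles for the suite

.helper_env <- new.env(parent = emptyenv())

# the seed-42 fixture set, generated once per test run
test_fixtures <- function() {
  if (is.null(.helper_env$fx)) .helper_env$fx <- generate_fixtures(42L)
  .helper_env$fx
}

test_registry <- function() test_fixtures()$registry

quiet <- function(expr) suppressMessages(expr)

# naive canonical rotation: minimum over all rotations of both strands
naive_canonical <- function(seq) {
  rots <- function(s) {
    n <- nchar(s)
    vapply(0:(n - 1L), function(k)
      paste0(substr(s, k + 1L, n), substr(s, 1L, k)), character(1L))
  }
  min(c(rots(seq), rots(revcomp(seq))))
}

# independent site counting through Biostrings (doubled string for circles)
oracle_site_count <- function(seq, recognition, circular = FALSE) {
  subject <- if (circular && nchar(seq) >= nchar(recognition))
    paste0(seq, substr(seq, 1L, nchar(recognition) - 1L)) else seq
  Biostrings::countPattern(recognition, Biostrings::DNAString(subject))
}

# brute-force digestion oracle: rotate a circular sequence to put the first
# top-strand cut at the origin, then cut linearly; returns sorted fragment
# lengths
oracle_circular_fragment_lengths <- function(seq, enzyme_names) {
  L <- nchar(seq)
  cuts <- integer()
  for (nm in enzyme_names) {
    e <- enz(nm)
    doubled <- paste0(seq, substr(seq, 1L, nchar(e$recognition) - 1L))
    m <- gregexpr(e$recognition, doubled, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) next
    starts <- as.integer(m) - 1L
    starts <- starts[starts < L]
    cuts <- c(cuts, (starts + e$cut_top) %% L)
  }
  cuts <- sort(unique(cuts))
  if (!length(cuts)) return(integer())
  rotated_cuts <- sort((cuts - cuts[1L]) %% L)
  sort(diff(c(rotated_cuts, L)))
}

# random molecule with sites planted at spaced positions (plus whatever
# occurs by chance)
random_molecule_with_sites <- function(len, n_sites, site_pool = names(enzymes())) {
  base <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  if (n_sites > 0L) {
    slots <- seq(1L, len - 6L, by = 12L)
    at <- sample(slots, min(n_sites, length(slots)))
    for (p in at) {
      rec <- enz(sample(site_pool, 1L))$recognition
      substr(base, p, p + 5L) <- rec
    }
  }
  dna(base, "circular")
}

# independent brute-force circular-ligation enumerator over 1-2 fragments:
# tries every relative orientation, joining ends by explicit sticky-end
# matching, and returns the set of naive-canonical product sequences
oracle_ligation_products <- function(frags) {
  # explicit duplex flip from first principles: lay out the full column
  # extent, take the bottom strand's extent, read it 5'->3'
  flip <- function(f) {
    le <- f$left_end; re <- f$right_end
    E <- paste0(if (le$kind == "three_prime") revcomp(le$overhang) else "",
                f$seq,
                if (re$kind == "five_prime") revcomp(re$overhang) else "")
    bs <- if (le$kind == "five_prime") nchar(le$overhang) else 0L
    be <- nchar(E) - if (re$kind == "three_prime") nchar(re$overhang) else 0L
    dna(revcomp(substr(E, bs + 1L, be)), "linear",
        left_end = re, right_end = le)
  }
  joinable <- function(right, left) {
    if (right$kind == "blunt" && left$kind == "blunt") return(TRUE)
    right$kind == left$kind &&
      nchar(right$overhang) == nchar(left$overhang) &&
      right$overhang == revcomp(left$overhang)
  }
  out <- character()
  if (length(frags) == 1L) {
    f <- frags[[1L]]
    if (joinable(f$right_end, f$left_end)) out <- c(out, naive_canonical(f$seq))
  } else {
    a <- frags[[1L]]
    for (b in list(frags[[2L]], flip(frags[[2L]]))) {
      if (joinable(a$right_end, b$left_end) && joinable(b$right_end, a$left_end))
        out <- c(out, naive_canonical(paste0(a$seq, b$seq)))
    }
  }
  sort(unique(out))
}

# random short protein starting with Met
random_protein <- function(n) {
  aas <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], "M")
  paste0("M", paste(sample(aas, n - 1L, replace = TRUE), collapse = ""))
}
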