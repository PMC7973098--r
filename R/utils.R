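## Internal helpers shared across stages.

# Sub-seed derivation: every generated artifact draws from its own stream,
# seeded as master + fixed offset, so any single fixture can be regenerated
# independently of the others. Offsets are part of the package contract.
.SEED_OFFSETS <- c(screen = 1L, ct = 2L, genome = 3L, phenotype = 4L)

sub_seed <- function(master, artifact) {
  stopifnot(artifact %in% names(.SEED_OFFSETS))
  master <- as.integer(master)
  (master %% .Machine$integer.max) + .SEED_OFFSETS[[artifact]]
}

# Evaluate expr under a local RNG state seeded with `seed`; the caller's
# RNG stream is left untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Significance stars from a p-value
#'
#' Maps a p-value to the conventional star annotation used on screen and
#' phenotype figures: `****` p <= 1e-4, `***` p <= 1e-3, `**` p <= 0.01,
#' `*` p <= 0.05, `ns` otherwise.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return character vector of the same length.
#' @export
stars_from_p <- function(p) {
  stopifnot(is.numeric(p), all(is.na(p) | (p >= 0 & p <= 1)))
  out <- rep("ns", length(p))
  out[!is.na(p) & p <= 0.05]   <- "*"
  out[!is.na(p) & p <= 0.01]   <- "**"
  out[!is.na(p) & p <= 0.001]  <- "***"
  out[!is.na(p) & p <= 0.0001] <- "****"
  out[is.na(p)] <- NA_character_
  out
}

# Append an exclusion record (well/gene/peak dropped, with reason code) to a
# log data.frame. Every stage reports its exclusions through this.
exclusion_record <- function(stage, item, reason) {
  data.frame(stage = stage, item = item, reason = reason,
             stringsAsFactors = FALSE)
}

empty_exclusions <- function() {
  data.frame(stage = character(), item = character(), reason = character(),
             stringsAsFactors = FALSE)
}

# Well-name helpers for rectangular plates. Wells are addressed row-letter +
# column-number ("A1".."P24" on a 384-well plate), ordered column-major.
well_names <- function(rows, cols) {
  stopifnot(rows >= 1, cols >= 1, rows <= 26)
  as.vector(outer(LETTERS[seq_len(rows)], seq_len(cols), paste0))
}
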