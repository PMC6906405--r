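# Internal helpers shared across modules.

# Strip a leading "chr"/"Chr" prefix so cohorts on different labelling
# conventions compare equal.
norm_chrom <- function(x) sub("^chr", "", as.character(x), ignore.case = TRUE)

# Canonical biallelic variant key "chrom:pos:REF:ALT".
make_variant_key <- function(chrom, pos, ref, alt) {
  paste(norm_chrom(chrom), as.integer(pos), toupper(ref), toupper(alt),
        sep = ":")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(..., call. = FALSE)

# Small assertion helper: scalar numeric in a closed range.
check_prob <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi)
    stop_param(sprintf("'%s' must be a single number in [%g, %g]",
                       name, lo, hi))
  invisible(x)
}
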