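# Internal helpers shared across modules.

# Round half away from zero (0.5 -> 1, -0.5 -> -1); base round() uses
# banker's rounding, which would misplace scores sitting on the
# below-zero classification boundary.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Split a ";"-delimited serialised list field; "" and NA give character(0).
split_field <- function(x, sep = ";") {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, sep, fixed = TRUE)[[1]])
}

join_field <- function(x, sep = ";") paste(x, collapse = sep)

`%||%` <- function(a, b) if (is.null(a)) b else a
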