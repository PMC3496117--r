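# internal helpers shared across modules

# upper-case, trimmed gene symbols; all matching happens on this form
normalize_genes <- function(x) toupper(trimws(as.character(x)))

# locale-independent sort so outputs are byte-identical across machines
sort_c <- function(x) sort(x, method = "radix")

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 1 && x == floor(x)

check_fraction <- function(x, name, lo = 0, hi = 1, lo_open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) && x <= hi
  if (!ok) {
    abort(sprintf("`%s` must be a single number in %s%s, %s]",
                  name, if (lo_open) "(" else "[", lo, hi))
  }
  invisible(x)
}

# deterministic derivation of per-stage RNG substreams from one master seed
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629)
}

write_tsv_det <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
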