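`%||%` <- function(a, b) if (is.null(a)) b else a

# Locale-independent (C collation) elementwise string min/max, used for the
# canonical unordered edge key so results do not depend on the session locale.
c_locale_le <- function(a, b) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  a <= b
}

pmin_chr <- function(a, b) ifelse(c_locale_le(a, b), a, b)
pmax_chr <- function(a, b) ifelse(c_locale_le(a, b), b, a)

edge_label <- function(a, b) paste(a, b, sep = "|")

join_sources <- function(x) paste(sort_c(unique(x)), collapse = ";")

split_sources <- function(x) strsplit(x, ";", fixed = TRUE)

# Deterministic C-locale sort / order
sort_c <- function(x) x[order(x, method = "radix")]

order_c <- function(...) order(..., method = "radix")
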