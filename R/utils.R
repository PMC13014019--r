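#' @importFrom rlang %||%
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

# Derive a child seed < 2^31 from a master seed and a stream label.
derive_seed <- function(master_seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(master_seed) * 1103 + h * 12289 + 49297) %% 2147483629) + 1L
}
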