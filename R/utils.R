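# internal error helpers: all conditions carry an adaptbias_* class so callers
# can distinguish geometry errors from statistical/domain errors

abort_geometry <- function(msg) rlang::abort(msg, class = "adaptbias_geometry_error")
abort_empty <- function(msg) rlang::abort(msg, class = "adaptbias_empty_structure_error")
abort_domain <- function(msg) rlang::abort(msg, class = "adaptbias_domain_error")
abort_patch <- function(msg) rlang::abort(msg, class = "adaptbias_inconsistent_patch_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

# derive a reproducible child seed (< 2^31) from a parent seed and a stage tag
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483647)
}
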