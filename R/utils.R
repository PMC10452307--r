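# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# 95% normal CI multiplier; kept at full precision, not 1.96.
Z95 <- stats::qnorm(0.975)

mr_error <- function(msg, class) {
  stop(structure(
    class = c(class, "mr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

config_error <- function(msg) mr_error(msg, "mr_config_error")
data_error <- function(msg) mr_error(msg, "mr_data_error")
domain_error <- function(msg) mr_error(msg, "mr_domain_error")
insufficient_instruments_error <- function(msg) {
  mr_error(msg, "mr_insufficient_instruments")
}

new_exclusion_log <- function() {
  data.frame(snp_id = character(), stage = character(), reason = character(),
             stringsAsFactors = FALSE)
}

log_exclusions <- function(log, snp_id, stage, reason) {
  if (length(snp_id) == 0L) return(log)
  rbind(log, data.frame(snp_id = as.character(snp_id), stage = stage,
                        reason = reason, stringsAsFactors = FALSE))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
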