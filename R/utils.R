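# internal helpers shared across modules

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# stable per-(participant, condition) RNG stream derived from one master seed;
# kept below 2^31 so the result is always a valid integer seed
stream_seed <- function(master, participant, condition_index) {
  (as.double(master) + 1000003 * participant + 7919 * condition_index) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
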