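# shared fixtures built in code

# a minimal 4-gel gelset (one subject per group) from explicit volumes
tiny_gelset <- function(volumes = NULL, n_spots = 6) {
  if (is.null(volumes)) {
    volumes <- matrix(10 * seq_len(n_spots * 4), n_spots, 4)
  }
  rownames(volumes) <- sprintf("s%02d", seq_len(nrow(volumes)))
  colnames(volumes) <- c("NH01_pos", "NH01_neg", "HF01_pos", "HF01_neg")
  meta <- data.frame(
    gel_id = colnames(volumes),
    subject_id = rep(c("NH01", "HF01"), each = 2),
    group = rep(c("NH", "HF"), each = 2),
    channel = rep(c("Asc+", "Asc-"), 2),
    stringsAsFactors = FALSE)
  gelset(volumes, meta)
}

# near-noiseless null configuration (validation requires technical_cov > 0)
quiet_config <- function(...) {
  synthetic_config(technical_cov = 1e-9, bias_log_sd = 0, biological_cov = 0,
                   ...)
}

# gel ids for one group/channel cell, from the metadata table
.gels_for_test <- function(gs, group = NULL, channel = NULL) {
  m <- gs$gel_meta
  keep <- rep(TRUE, nrow(m))
  if (!is.null(group)) keep <- keep & m$group == group
  if (!is.null(channel)) keep <- keep & m$channel == channel
  m$gel_id[keep]
}

# mark a gelset as normalized without rescaling (for exact-ratio tests on
# hand-built volumes)
as_normalized <- function(gs) {
  gs$normalized <- TRUE
  gs$reference_gel <- colnames(gs$volumes)[1L]
  gs
}
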