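# Shared fixture builders (everything is generated in code).

# A keylog data frame for a single trial from a vector of symbolic keys.
make_trial_events <- function(keys, pid = "p1", trial = 1L,
                              item_id = "i1", t0 = 800, step = 200) {
  n <- length(keys)
  data.frame(pid = rep(pid, n), trial = rep(as.integer(trial), n),
             item_id = rep(item_id, n), key = keys,
             t_ms = t0 + step * (seq_len(n) - 1L),
             stringsAsFactors = FALSE)
}

# The worked-example stimuli used throughout the classification tests.
worked_stimuli <- function() {
  data.frame(
    item_id = c("schloss", "feile", "kelle", "spueler", "tisch"),
    name = c("SCHLOSS", "FEILE", "KELLE", "GESCHIRRSPÜLER", "TISCH"),
    alternatives = c("BURG", "", "", "", ""),
    category = c("buildings", "tools", "tools", "household", "furniture"),
    superordinate = c("artefacts", "artefacts", "artefacts", "artefacts",
                      "artefacts"),
    is_filler = FALSE, stringsAsFactors = FALSE)
}

chars <- function(word) strsplit(word, "")[[1]]

# Reconstruct-and-classify a single trial given its key sequence.
classify_keys <- function(keys, stimulus, config = match_config()) {
  ev <- make_trial_events(keys, item_id = stimulus$item_id)
  entry <- reconstruct_entry(strip_terminal_keys(ev))
  classify_entry(entry, stimulus, config)
}
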