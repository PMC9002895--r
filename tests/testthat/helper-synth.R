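# Shared fixtures, built in code. Heavier objects are cached per session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# a clean 10-s, 60-bpm record and its normalized first lead
clean_record <- function() {
  fixture("clean10", function() generate_record(synth_params(duration = 10)))
}

clean_lead <- function() {
  fixture("clean10lead",
          function() minmax_normalize(clean_record()$signal$MLII))
}

# normalized copy of a record (all leads)
normalize_record <- function(rec) {
  rec$signal <- lapply(rec$signal, minmax_normalize)
  rec
}

# fraction of annotated beats found within tol_s by a detector result
recall_within <- function(found, truth, tol_samples) {
  if (length(truth) == 0) return(NA_real_)
  mean(vapply(truth, function(t) any(abs(found - t) <= tol_samples),
              logical(1)))
}
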