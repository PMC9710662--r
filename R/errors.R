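# Classed conditions so callers (and the CLI) can react to specific failures.

abort_genecat <- function(class, msg, ...) {
  cond <- structure(
    class = c(class, "genecat_error", "error", "condition"),
    list(message = msg, call = sys.call(-1L), ...)
  )
  stop(cond)
}

# condition classes used throughout:
#   genecat_duplicate_marker_error   genecat_duplicate_sample_error
#   genecat_alphabet_error           genecat_token_error
#   genecat_unknown_marker_error     genecat_invalid_order_error
#   genecat_format_error             genecat_empty_input_error
#   genecat_not_aligned_error        genecat_partition_error
#   genecat_name_collision_error     genecat_insufficient_data_error
#   genecat_unknown_format_error     genecat_spec_error
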