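# internal helpers shared across modules

# gap in bp between two half-open intervals on the same chromosome; 0 if they
# overlap or touch-at-zero is impossible since start < end
interval_gap <- function(start1, end1, start2, end2) {
  pmax(0L, pmax(start2 - end1 + 1L, start1 - end2 + 1L) - 1L)
}

# distance convention used for island/shore/gene-subset calls: number of bases
# strictly between the intervals (0 when they overlap or abut)
interval_distance <- function(start1, end1, start2, end2) {
  pmax(0, pmax(start2 - end1, start1 - end2))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]",
                  name, format(lower), format(upper)),
          class = "dmrbeta_config_error")
  }
  invisible(x)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(missing, collapse = ", ")),
          class = "dmrbeta_format_error")
  }
  invisible(df)
}

group_label <- function(genotype, treatment) paste(genotype, treatment, sep = "_")

# resolve a "KO_HDM" style label against the sample design
samples_in_group <- function(design, label) {
  design$sample[group_label(design$genotype, design$treatment) == label]
}

check_contrast <- function(design, contrast) {
  if (length(contrast) != 2L) {
    abort("`contrast` must be two group labels like c('KO_HDM', 'WT_HDM')",
          class = "dmrbeta_config_error")
  }
  for (g in contrast) {
    if (length(samples_in_group(design, g)) == 0L) {
      abort(sprintf("contrast group '%s' has no samples in the design", g),
            class = "dmrbeta_config_error")
    }
  }
  invisible(contrast)
}
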