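# Build an effect_estimate directly from a log OR and its standard error,
# bypassing the 2x2 route, for closed-form pooling checks.
make_effect <- function(y, se) {
  structure(
    list(
      log_or = y, se = se, or = exp(y),
      ci_low = exp(y - 1.96 * se), ci_high = exp(y + 1.96 * se)
    ),
    class = "effect_estimate"
  )
}

make_effects <- function(y, se) Map(make_effect, y, se)

# Published per-row values for the bundled rs671/gastric-cancer collection:
# pooled OR, 95% CI, raw p and I2 (percent) for each (category, model) row
# that the source report prints for the overall and country subgroups.
published_rows <- function() {
  read.csv(text = 'category,model,or,ci_low,ci_high,p,i2
Overall,hom,1.101,0.924,1.313,0.282,23.2
Overall,het,1.030,0.959,1.106,0.423,12.7
Overall,allele,1.031,0.972,1.093,0.310,10.9
Overall,recessive,1.067,0.898,1.268,0.461,20.6
Overall,dominant,1.033,0.963,1.107,0.365,13.8
Japan,allele,1.138,1.010,1.281,0.034,0.0
Japan,dominant,1.172,1.008,1.364,0.040,0.0
Korea,recessive,0.563,0.314,1.008,0.053,0.0
Korea,hom,0.592,0.329,1.064,0.080,0.0', stringsAsFactors = FALSE)
}

# The published unadjusted p column by category, in model order
# hom, het, allele, recessive, dominant (the multiplicity family inputs).
published_p_families <- function() {
  list(
    Overall = c(0.282, 0.423, 0.310, 0.461, 0.365),
    China   = c(0.380, 0.431, 0.815, 0.389, 0.554),
    Japan   = c(0.087, 0.076, 0.034, 0.220, 0.040),
    Korea   = c(0.080, 0.093, 0.659, 0.053, 0.365),
    HB      = c(0.926, 0.435, 0.647, 0.799, 0.526),
    PB      = c(0.074, 0.801, 0.229, 0.088, 0.476)
  )
}

# Published Bonferroni and FDR columns in the same order.
published_adjusted <- function() {
  list(
    bon = list(
      Overall = c(1.000, 1.000, 1.000, 1.000, 1.000),
      China   = c(1.000, 1.000, 1.000, 1.000, 1.000),
      Japan   = c(0.435, 0.380, 0.170, 1.000, 0.200),
      Korea   = c(0.400, 0.465, 1.000, 0.265, 1.000),
      HB      = c(1.000, 1.000, 1.000, 1.000, 1.000),
      PB      = c(0.370, 1.000, 1.000, 0.440, 1.000)
    ),
    fdr = list(
      Overall = c(0.461, 0.461, 0.461, 0.461, 0.461),
      China   = c(0.693, 0.693, 0.815, 0.693, 0.693),
      Japan   = c(0.109, 0.109, 0.100, 0.220, 0.100),
      Korea   = c(0.155, 0.155, 0.659, 0.155, 0.456),
      HB      = c(0.926, 0.926, 0.926, 0.926, 0.926),
      PB      = c(0.220, 0.801, 0.381, 0.220, 0.595)
    )
  )
}
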