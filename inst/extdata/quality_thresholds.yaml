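# Example soil-quality thresholds -- SYNTHETIC PLACEHOLDER VALUES.
#
# Four strictly increasing breakpoints per (variable, context) bound the
# five categories very_low / low / normal / high / very_high; a value on a
# breakpoint belongs to the higher category. Contexts allow land-use- or
# soil-type-specific guideline bands; "default" is the fallback. These
# numbers are illustrative only and are NOT regulatory guideline values:
# replace them with your jurisdiction's guidelines for real assessments.
categories: [very_low, low, normal, high, very_high]
variables:
  pH:
    optimal: normal
    contexts:
      default: [5.0, 5.5, 6.2, 6.6]
  C_pct:
    optimal: normal
    contexts:
      default: [2.0, 4.0, 7.0, 12.0]
  TN_pct:
    optimal: normal
    contexts:
      default: [0.15, 0.25, 0.60, 0.80]
  AMN:
    optimal: normal
    contexts:
      default: [25, 50, 125, 200]
  OlsenP:
    optimal: normal
    contexts:
      default: [10, 20, 50, 100]
  MP:
    optimal: normal
    contexts:
      default: [6, 10, 25, 40]
  BD:
    optimal: normal
    contexts:
      default: [0.8, 1.0, 1.3, 1.6]
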