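# Named generator scenarios. Conditions are always in the canonical order
# old word, old nonword, new word, new nonword; each row of `probs` is the
# condition-level (remember, know, new) response-probability baseline.
# Probabilities are taken from printed, rounded summary tables and are
# therefore approximate; rows are renormalized to the simplex at load time.
# `tilt` (optional) adds the given value to the remember-vs-know log odds of
# every word or nonword condition before use, leaving the new-response mass
# untouched -- a lexicality bias of the kind the ordered models describe.
# `heterogeneity_sd` is the SD of the participant-level remember-vs-know
# preference shift on the log-odds scale, shared across conditions.

gardiner_java:
  description: >
    The original crossover pattern: remember preferred for old words, know
    for old nonwords, no lexicality effect for lures.
  probs:
    old_word:    [0.28, 0.16, 0.56]
    old_nonword: [0.19, 0.30, 0.51]
    new_word:    [0.04, 0.11, 0.85]
    new_nonword: [0.03, 0.12, 0.85]
  heterogeneity_sd: 1.5

null_lexicality:
  description: >
    No lexicality effect for old or new items (the single-process pattern
    observed in the first replication experiment).
  probs:
    old_word:    [0.35, 0.30, 0.35]
    old_nonword: [0.36, 0.28, 0.37]
    new_word:    [0.20, 0.18, 0.61]
    new_nonword: [0.20, 0.15, 0.64]
  heterogeneity_sd: 1.5

word_bias:
  description: >
    Words promote remember responses regardless of study status: the
    null-lexicality baseline tilted towards remember for words and towards
    know for nonwords.
  probs:
    old_word:    [0.35, 0.30, 0.35]
    old_nonword: [0.36, 0.28, 0.37]
    new_word:    [0.20, 0.18, 0.61]
    new_nonword: [0.20, 0.15, 0.64]
  tilt: {word: 0.6, nonword: -0.6}
  heterogeneity_sd: 1.5

nonword_bias:
  description: >
    Nonwords promote remember responses regardless of study status; the
    mirror image of word_bias.
  probs:
    old_word:    [0.35, 0.30, 0.35]
    old_nonword: [0.36, 0.28, 0.37]
    new_word:    [0.20, 0.18, 0.61]
    new_nonword: [0.20, 0.15, 0.64]
  tilt: {word: -0.6, nonword: 0.6}
  heterogeneity_sd: 1.5
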