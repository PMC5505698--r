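# Shared constants: strand-collapsed substitution classes.
spectrum_classes <- c("A:T>G:C", "G:C>A:T", "A:T>C:G",
                      "A:T>T:A", "G:C>C:G", "G:C>T:A")
transition_classes <- c("A:T>G:C", "G:C>A:T")

# class -> (plus-strand representative ref, alt) and its complement row
class_pairs <- data.frame(
  class = rep(spectrum_classes, each = 2),
  ref = c("A", "T",  "G", "C",  "A", "T",  "A", "T",  "G", "C",  "G", "C"),
  alt = c("G", "C",  "A", "T",  "C", "G",  "T", "A",  "C", "G",  "T", "A")
)
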