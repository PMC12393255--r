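## instruction
Paraphrase the following research interest profile. Preserve its meaning
and coverage while changing the wording and sentence structure.

## example_input
My laboratory studies how neurons form circuits during development.

## example_output
The lab investigates the developmental assembly of neuronal circuits.
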