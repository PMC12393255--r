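## instruction
You are given several short topic summaries of one researcher's work.
Combine them into a single coherent research interest profile in the third
person, without repeating sentences.

## example_input
The researcher builds deep learning models for medical imaging.
The researcher studies outcomes of cancer screening programs.

## example_output
The researcher develops deep learning methods for medical imaging and
evaluates their impact on cancer screening outcomes.
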