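## instruction
You are given a set of publication abstracts by one researcher on a shared
topic. Condense them into one succinct paragraph describing the research
interests they reflect, in the third person.

## example_input
We developed a deep learning model to detect tumors in radiology images.
Our model improves sensitivity over prior screening approaches.

## example_output
The researcher builds deep learning models for tumor detection in medical
imaging, improving the sensitivity of screening.
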