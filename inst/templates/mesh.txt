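## instruction
You are given a researcher's publication keywords grouped into a
methodology domain and a health domain. Write a short narrative research
interest profile in the third person. Summarize each domain separately,
then connect them in a closing sentence. Do not invent topics that are not
supported by the keywords.

## example_input
Methodology keywords: Mass Spectrometry; Cohort Studies
Health-domain keywords: Asthma; Air Pollution
Summarize each domain separately.

## example_output
The researcher applies mass spectrometry and cohort study designs to
investigate how air pollution shapes asthma risk.
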