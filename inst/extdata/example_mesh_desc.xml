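<?xml version="1.0" encoding="UTF-8"?>
<DescriptorRecordSet>
  <DescriptorRecord>
    <DescriptorName><String>Natural Language Processing</String></DescriptorName>
    <TreeNumberList><TreeNumber>L01.224.050.375.580</TreeNumber></TreeNumberList>
    <ConceptList>
      <Concept>
        <TermList>
          <Term><String>Natural Language Processing</String></Term>
          <Term><String>NLP</String></Term>
          <Term><String>Computational Linguistics</String></Term>
        </TermList>
      </Concept>
    </ConceptList>
  </DescriptorRecord>
  <DescriptorRecord>
    <DescriptorName><String>Neoplasms</String></DescriptorName>
    <TreeNumberList><TreeNumber>C04</TreeNumber></TreeNumberList>
    <ConceptList>
      <Concept>
        <TermList>
          <Term><String>Neoplasms</String></Term>
          <Term><String>Tumors</String></Term>
          <Term><String>Cancer</String></Term>
        </TermList>
      </Concept>
    </ConceptList>
  </DescriptorRecord>
  <DescriptorRecord>
    <DescriptorName><String>Machine Learning</String></DescriptorName>
    <TreeNumberList><TreeNumber>G17.035.250.500</TreeNumber><TreeNumber>L01.224.050.375.530</TreeNumber></TreeNumberList>
    <ConceptList>
      <Concept>
        <TermList>
          <Term><String>Machine Learning</String></Term>
        </TermList>
      </Concept>
    </ConceptList>
  </DescriptorRecord>
  <DescriptorRecord>
    <DescriptorName><String>Rare Diseases</String></DescriptorName>
    <TreeNumberList><TreeNumber>C23.550.288.500</TreeNumber></TreeNumberList>
    <ConceptList>
      <Concept>
        <TermList>
          <Term><String>Rare Diseases</String></Term>
          <Term><String>Orphan Diseases</String></Term>
        </TermList>
      </Concept>
    </ConceptList>
  </DescriptorRecord>
  <DescriptorRecord>
    <DescriptorName><String>Periodicals as Topic</String></DescriptorName>
    <TreeNumberList><TreeNumber>V01.324.500</TreeNumber></TreeNumberList>
    <ConceptList>
      <Concept>
        <TermList>
          <Term><String>Periodicals as Topic</String></Term>
        </TermList>
      </Concept>
    </ConceptList>
  </DescriptorRecord>
</DescriptorRecordSet>
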