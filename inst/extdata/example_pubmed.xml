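<?xml version="1.0" encoding="UTF-8"?>
<PubmedArticleSet>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>1000001</PMID>
      <Article>
        <Journal>
          <JournalIssue>
            <PubDate><Year>2022</Year></PubDate>
          </JournalIssue>
        </Journal>
        <ArticleTitle>Deep phenotyping of rare disease cohorts</ArticleTitle>
        <Abstract>
          <AbstractText>We describe a framework for deep phenotyping of rare disease cohorts using structured clinical data.</AbstractText>
        </Abstract>
        <AuthorList>
          <Author>
            <LastName>Rivera</LastName>
            <ForeName>Dana</ForeName>
            <AffiliationInfo><Affiliation>Synthetic Medical Center</Affiliation></AffiliationInfo>
          </Author>
          <Author>
            <LastName>Okafor</LastName>
            <ForeName>Chidi</ForeName>
          </Author>
        </AuthorList>
      </Article>
      <MeshHeadingList>
        <MeshHeading>
          <DescriptorName MajorTopicYN="Y">Rare Diseases</DescriptorName>
        </MeshHeading>
        <MeshHeading>
          <DescriptorName MajorTopicYN="N">Natural Language Processing</DescriptorName>
        </MeshHeading>
      </MeshHeadingList>
    </MedlineCitation>
  </PubmedArticle>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>1000002</PMID>
      <Article>
        <Journal>
          <JournalIssue>
            <PubDate><Year>2019</Year></PubDate>
          </JournalIssue>
        </Journal>
        <ArticleTitle>A registry without an abstract</ArticleTitle>
        <AuthorList>
          <Author>
            <LastName>Rivera</LastName>
            <ForeName>Dana</ForeName>
          </Author>
          <Author>
            <LastName>Chen</LastName>
            <ForeName>Li</ForeName>
          </Author>
          <Author>
            <LastName>Mueller</LastName>
            <ForeName>Anna</ForeName>
          </Author>
        </AuthorList>
      </Article>
    </MedlineCitation>
  </PubmedArticle>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>1000003</PMID>
      <Article>
        <Journal>
          <JournalIssue>
            <PubDate><MedlineDate>2015 Jan-Feb</MedlineDate></PubDate>
          </JournalIssue>
        </Journal>
        <ArticleTitle>Screening outcomes in community clinics</ArticleTitle>
        <Abstract>
          <AbstractText>Background text.</AbstractText>
          <AbstractText>Results text.</AbstractText>
        </Abstract>
        <AuthorList>
          <Author>
            <LastName>Okafor</LastName>
            <ForeName>Chidi</ForeName>
          </Author>
          <Author>
            <LastName>Rivera</LastName>
            <ForeName>Dana</ForeName>
          </Author>
        </AuthorList>
      </Article>
      <MeshHeadingList>
        <MeshHeading>
          <DescriptorName MajorTopicYN="N">Neoplasms</DescriptorName>
        </MeshHeading>
      </MeshHeadingList>
    </MedlineCitation>
  </PubmedArticle>
</PubmedArticleSet>
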