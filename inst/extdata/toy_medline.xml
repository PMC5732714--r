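<?xml version="1.0" encoding="UTF-8"?>
<PubmedArticleSet>
<PubmedArticle>
  <MedlineCitation>
    <PMID>10000001</PMID>
    <Article>
      <ArticleTitle>Apoptosis and cancer.</ArticleTitle>
      <Abstract>
        <AbstractText>Apoptosis regulates cancer. Angiosarcoma cells resist apoptosis.</AbstractText>
      </Abstract>
    </Article>
  </MedlineCitation>
</PubmedArticle>
<PubmedArticle>
  <MedlineCitation>
    <PMID>10000002</PMID>
    <Article>
      <ArticleTitle>A structured abstract.</ArticleTitle>
      <Abstract>
        <AbstractText Label="BACKGROUND">Eccrine porocarcinoma is rare.</AbstractText>
        <AbstractText Label="RESULTS">Porocarcinoma shares genes with cancer.</AbstractText>
      </Abstract>
    </Article>
  </MedlineCitation>
</PubmedArticle>
<PubmedArticle>
  <MedlineCitation>
    <PMID>10000003</PMID>
    <Article>
      <ArticleTitle>Osteochondrodysplasia review.</ArticleTitle>
      <Abstract>
        <AbstractText>Osteochondrodysplasia affects bone. E. coli infection complicates 3.5 percent of cases. Malignant tumor growth was absent.</AbstractText>
      </Abstract>
    </Article>
  </MedlineCitation>
</PubmedArticle>
<PubmedArticle>
  <MedlineCitation>
    <PMID>10000004</PMID>
    <Article>
      <ArticleTitle>No abstract here.</ArticleTitle>
    </Article>
  </MedlineCitation>
</PubmedArticle>
<PubmedArticle>
  <MedlineCitation>
    <PMID>10000005</PMID>
    <Article>
      <ArticleTitle>Disease associations.</ArticleTitle>
      <Abstract>
        <AbstractText>Cancer and osteochondrodysplasia rarely co-occur. Angiosarcoma is a malignancy.</AbstractText>
      </Abstract>
    </Article>
  </MedlineCitation>
</PubmedArticle>
</PubmedArticleSet>
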