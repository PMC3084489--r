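<?xml version="1.0" encoding="UTF-8"?>
<article dtd-version="tp-subset-1.0">
  <front>
    <journal-meta>
      <journal-title>PhytoKeys</journal-title>
    </journal-meta>
    <article-meta>
      <title-group>
        <article-title>New and poorly known species of Piociamious from synthetic localities</article-title>
      </title-group>
      <contrib-group>
        <contrib>
          <surname>Platruzae</surname>
          <given-names>N C</given-names>
        </contrib>
        <contrib>
          <surname>Brucrikia</surname>
          <given-names>K</given-names>
        </contrib>
        <contrib>
          <surname>Ciochia</surname>
          <given-names>L B</given-names>
        </contrib>
      </contrib-group>
      <pub-date>
        <day>20</day>
        <month>05</month>
        <year>2011</year>
      </pub-date>
      <issue>16</issue>
      <fpage>10</fpage>
      <lpage>31</lpage>
      <article-id pub-id-type="doi">10.9999/synthetic.14.5305</article-id>
    </article-meta>
  </front>
  <body>
    <taxon-treatment>
      <nomenclature>
        <taxon-name>
          <taxon-name-part part-type="genus">Cheziacraus</taxon-name-part>
          <taxon-name-part part-type="species">haebraezuatus</taxon-name-part>
        </taxon-name>
        <taxon-authority>Ciochia, 2011</taxon-authority>
        <object-id id-type="zoobank">urn:lsid:zoobank.org:act:00FDBD8C</object-id>
        <classification>
          <rank name="order">Chabioida</rank>
          <rank name="family">Thiphioidae</rank>
        </classification>
      </nomenclature>
      <treatment-sec sec-title="Distribution">
        <p>Synthetic distribution text for Cheziacraus haebraezuatus (paragraph 1).</p>
        <fig-ref rid="F1-1"/>
      </treatment-sec>
      <treatment-sec sec-title="Etymology">
        <p>Synthetic etymology text for Cheziacraus haebraezuatus (paragraph 2).</p>
      </treatment-sec>
      <treatment-sec sec-title="Materials examined">
        <p>Synthetic materials examined text for Cheziacraus haebraezuatus (paragraph 3).</p>
      </treatment-sec>
      <treatment-sec sec-title="Remarks">
        <p>Synthetic remarks text for Cheziacraus haebraezuatus (paragraph 4).</p>
      </treatment-sec>
      <ref-list>
        <ref id="B1-1">Synthetic reference 1 for Cheziacraus haebraezuatus.</ref>
      </ref-list>
      <fig id="F1-1">
        <caption>Cheziacraus haebraezuatus, synthetic figure 1.</caption>
        <graphic href="source_image_1_1.png"/>
      </fig>
      <fig id="F1-2">
        <caption>Cheziacraus haebraezuatus, synthetic figure 2.</caption>
        <graphic href="source_image_1_2.png"/>
      </fig>
    </taxon-treatment>
    <taxon-treatment>
      <nomenclature>
        <taxon-name>
          <taxon-name-part part-type="genus">Cheziacraus</taxon-name-part>
          <taxon-name-part part-type="species">piphiicus</taxon-name-part>
        </taxon-name>
        <taxon-authority>Platruzae, 2011</taxon-authority>
        <object-id id-type="zoobank">urn:lsid:zoobank.org:act:008CDB3F</object-id>
        <classification>
          <rank name="order">Treoceida</rank>
          <rank name="family">Zioniidae</rank>
        </classification>
      </nomenclature>
      <treatment-sec sec-title="Type locality">
        <p>Synthetic type locality text for Cheziacraus piphiicus (paragraph 1).</p>
        <coordinates latitude="-39.6000" longitude="-68.4000">-39.6000, -68.4000</coordinates>
        <fig-ref rid="F2-1"/>
      </treatment-sec>
      <treatment-sec sec-title="Diagnosis">
        <p>Synthetic diagnosis text for Cheziacraus piphiicus (paragraph 2).</p>
      </treatment-sec>
      <treatment-sec sec-title="Ecology">
        <p>Synthetic ecology text for Cheziacraus piphiicus (paragraph 3).</p>
      </treatment-sec>
      <treatment-sec sec-title="Materials examined">
        <p>Synthetic materials examined text for Cheziacraus piphiicus (paragraph 4).</p>
      </treatment-sec>
      <ref-list>
        <ref id="B2-1">Synthetic reference 1 for Cheziacraus piphiicus.</ref>
        <ref id="B2-2">Synthetic reference 2 for Cheziacraus piphiicus.</ref>
      </ref-list>
      <fig id="F2-1">
        <caption>Cheziacraus piphiicus, synthetic figure 1.</caption>
        <graphic href="source_image_2_1.png"/>
      </fig>
      <fig id="F2-2">
        <caption>Cheziacraus piphiicus, synthetic figure 2.</caption>
        <graphic href="source_image_2_2.png"/>
      </fig>
    </taxon-treatment>
  </body>
</article>
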