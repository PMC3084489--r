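<?xml version="1.0" encoding="UTF-8"?>
<!-- Hand-written example document in the pinned TaxPub subset.
     SYNTHETIC stand-in: the treatment text below is invented; only the
     taxon name, authorship and bibliographic skeleton mirror a real
     millipede description, so that page titles and URLs built from it
     are realistic. -->
<article dtd-version="tp-subset-1.0">
  <front>
    <journal-meta>
      <journal-title>ZooKeys</journal-title>
    </journal-meta>
    <article-meta>
      <title-group>
        <article-title>A review of the millipede genus Sinocallipus, with notes on cave-dwelling species</article-title>
      </title-group>
      <contrib-group>
        <contrib>
          <surname>Stoev</surname>
          <given-names>P</given-names>
        </contrib>
        <contrib>
          <surname>Enghoff</surname>
          <given-names>H</given-names>
        </contrib>
      </contrib-group>
      <pub-date>
        <day>14</day>
        <month>04</month>
        <year>2011</year>
      </pub-date>
      <issue>90</issue>
      <fpage>13</fpage>
      <lpage>34</lpage>
      <article-id pub-id-type="doi">10.9999/synthetic.90.0001</article-id>
    </article-meta>
  </front>
  <body>
    <taxon-treatment>
      <nomenclature>
        <taxon-name>
          <taxon-name-part part-type="genus">Sinocallipus</taxon-name-part>
          <taxon-name-part part-type="species">catba</taxon-name-part>
        </taxon-name>
        <taxon-authority>Stoev &amp; Enghoff, 2011</taxon-authority>
        <object-id id-type="zoobank">urn:lsid:zoobank.org:act:00000000-SYNTH-0001</object-id>
        <classification>
          <rank name="order">Callipodida</rank>
          <rank name="family">Sinocallipodidae</rank>
        </classification>
      </nomenclature>
      <treatment-sec sec-title="Type locality">
        <p>Synthetic locality text: a limestone cave on Cat Ba Island.</p>
        <coordinates latitude="20.7800" longitude="106.9800">20.7800, 106.9800</coordinates>
      </treatment-sec>
      <treatment-sec sec-title="Description">
        <p>Synthetic description text for a cave-dwelling callipodidan millipede.</p>
        <fig-ref rid="F1"/>
      </treatment-sec>
      <treatment-sec sec-title="Distribution">
        <p>Synthetic distribution text: known only from the type locality.</p>
      </treatment-sec>
      <treatment-sec sec-title="Etymology">
        <p>Synthetic etymology text: named after the island of origin.</p>
      </treatment-sec>
      <ref-list>
        <ref id="B1">Synthetic reference entry one.</ref>
        <ref id="B2">Synthetic reference entry two.</ref>
      </ref-list>
      <fig id="F1">
        <caption>Synthetic habitus drawing.</caption>
        <graphic href="habitus.png"/>
      </fig>
    </taxon-treatment>
  </body>
</article>
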