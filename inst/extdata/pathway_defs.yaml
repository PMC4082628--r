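# Curated, illustrative pathway definitions for the 14 fermentable
# substrates of the API 50 CH panel rows used in this package's examples.
# Gene lists follow common literature usage for lactobacilli (PTS systems,
# ABC transporters, glycoside hydrolases, Leloir and tagatose pathways) but
# are NOT an authoritative reconstruction of any particular genome
# annotation: they are editable data, not code.  Each substrate is a list
# of gene groups; a group is satisfied when at least one listed gene is
# intact, and the pathway is complete when every group is satisfied.
substrates:
  Galactose:
    - genes: [galP, lacS]
      transporter: true
    - genes: [galK]
    - genes: [galT]
    - genes: [galE]
  Glucose:
    - genes: [ptsG, glcU]
      transporter: true
    - genes: [glk]
  Fructose:
    - genes: [fruA]
      transporter: true
    - genes: [fruK]
  Mannose:
    - genes: [manX, manY, manZ]
      transporter: true
    - genes: [pmi]
  N-acetylglucosamine:
    - genes: [nagE]
      transporter: true
    - genes: [nagA]
    - genes: [nagB]
  Amygdalin:
    - genes: [bglP]
      transporter: true
    - genes: [bglB, bglA]
  Arbutin:
    - genes: [bglP, arbT]
      transporter: true
    - genes: [bglB, bglA]
  Esculin:
    - genes: [bglP, escT]
      transporter: true
    - genes: [bglB, bglA]
  Salicin:
    - genes: [bglP]
      transporter: true
    - genes: [bglB, bglA]
  Cellobiose:
    - genes: [celB, ptcA]
      transporter: true
    - genes: [pbg]
  Maltose:
    - genes: [malT, malEFG]
      transporter: true
    - genes: [mapA, malL]
  Lactose:
    - genes: [lacS, lacE]
      transporter: true
    - genes: [lacZ, lacLM, lacG]
  Sucrose:
    - genes: [scrA]
      transporter: true
    - genes: [scrB]
  Trehalose:
    - genes: [treB]
      transporter: true
    - genes: [treC]
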