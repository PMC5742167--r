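# Default label sets for the signed relatedness contrasts.
# valence: 18 positive / 18 negative everyday affect words (36 labels).
# ap: 62 positive / 62 negative aesthetic-vocabulary words (124 labels).
# Both lists are editable study inputs, not fixed vocabulary.
valence:
  name: valence
  positive:
    - geschenk
    - urlaub
    - fest
    - freund
    - lachen
    - erfolg
    - gewinn
    - genuss
    - lob
    - kuss
    - umarmung
    - heimat
    - familie
    - geburt
    - gesundheit
    - reichtum
    - sieg
    - spaß
  negative:
    - verlust
    - krieg
    - tod
    - angst
    - schmerz
    - trauer
    - wut
    - neid
    - betrug
    - lüge
    - strafe
    - unfall
    - krankheit
    - armut
    - niederlage
    - streit
    - feind
    - gefahr
ap:
  name: ap
  positive:
    - anmut
    - freude
    - liebe
    - glück
    - harmonie
    - zauber
    - glanz
    - schönheit
    - eleganz
    - grazie
    - melodie
    - poesie
    - traum
    - stern
    - blüte
    - rose
    - duft
    - frühling
    - sommer
    - sonne
    - licht
    - himmel
    - meer
    - welle
    - perle
    - seide
    - samt
    - gold
    - silber
    - kristall
    - regenbogen
    - schmetterling
    - libelle
    - nachtigall
    - lerche
    - quelle
    - bach
    - wiese
    - hain
    - abendrot
    - morgenröte
    - dämmerung
    - stille
    - sanftheit
    - zärtlichkeit
    - wonne
    - heiterkeit
    - gelassenheit
    - frieden
    - hoffnung
    - sehnsucht
    - geborgenheit
    - wärme
    - klang
    - schimmer
    - funkeln
    - leuchten
    - blühen
    - schweben
    - tanzen
    - singen
    - lächeln
  negative:
    - ekel
    - hass
    - schmutz
    - dreck
    - gestank
    - fäulnis
    - moder
    - schleim
    - eiter
    - kot
    - müll
    - abfall
    - ratte
    - made
    - wanze
    - zecke
    - kakerlake
    - schimmel
    - rost
    - ruß
    - qualm
    - gift
    - galle
    - übelkeit
    - wunde
    - geschwür
    - ausschlag
    - grind
    - kratzen
    - würgen
    - spucken
    - rülpsen
    - rotz
    - speichel
    - schweiß
    - mief
    - muff
    - matsch
    - morast
    - sumpf
    - jauche
    - kloake
    - gosse
    - verwesung
    - leiche
    - aas
    - geier
    - hyäne
    - kröte
    - egel
    - parasit
    - seuche
    - pest
    - grippe
    - husten
    - schleimig
    - klebrig
    - ranzig
    - faulig
    - bitter
    - schlamm
    - staub
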