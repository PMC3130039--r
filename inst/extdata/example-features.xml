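<?xml version="1.0" encoding="UTF-8"?>
<DASGFF>
<GFF version="1.0" href="http://example.org/das/demo/features?segment=chr1:1,1000">
<SEGMENT id="chr1" start="1" stop="1000">
<FEATURE id="ex1" label="first exon"><TYPE id="exon" category="transcription">exon</TYPE><METHOD id="curated">curated</METHOD><START>11</START><END>150</END><SCORE>             0.9</SCORE><ORIENTATION>+</ORIENTATION><PHASE>-</PHASE><GROUP id="tr1"/></FEATURE>
<FEATURE id="ex2"><TYPE id="exon" category="transcription">exon</TYPE><METHOD id="curated">curated</METHOD><START>501</START><END>700</END><SCORE>-</SCORE><ORIENTATION>-</ORIENTATION><PHASE>-</PHASE><GROUP id="tr1"/></FEATURE>
</SEGMENT>
</GFF>
</DASGFF>
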