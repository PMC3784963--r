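pattern	category	priority
ribosom	R	10
chaperon|cold[ -]?shock|GroE|DnaK|thioredoxin|peroxiredoxin|superoxide dismutase|alkyl hydroperoxide|redox	C	20
DNA[ -]?binding|transcription|regulator|helix[ -]?turn[ -]?helix|nucleoid|histone[ -]?like|sigma factor|RNA[ -]?binding|single[ -]?strand	D	30
uncharacteri[sz]ed|unknown function|hypothetical	U	40
ase\b|synthase|synthetase|dehydrogenase|kinase|reductase|transferase|hydrolase|membrane|transport|metabol	E	50
.*	U	100
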