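strain,species,lt50,se
ICIPE 07,Metarhizium anisopliae,5,0.6
ICIPE 18,Metarhizium anisopliae,4,0.2
ICIPE 20,Metarhizium anisopliae,13.3,2.3
ICIPE 30,Metarhizium anisopliae,7,0.5
ICIPE 32,Metarhizium anisopliae,30,6.4
ICIPE 40,Metarhizium anisopliae,9.3,1.4
ICIPE 41,Metarhizium anisopliae,18.5,5.4
ICIPE 62,Metarhizium anisopliae,13.4,4.4
ICIPE 69,Metarhizium anisopliae,4,0.25
ICIPE 78,Metarhizium anisopliae,17.5,10.8
ICIPE 603,Beauveria bassiana,11,2.3
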