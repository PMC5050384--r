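mary
patricia
jennifer
linda
elizabeth
barbara
susan
jessica
sarah
karen
nancy
lisa
margaret
betty
sandra
ashley
dorothy
kimberly
emily
donna
michelle
carol
amanda
melissa
deborah
stephanie
rebecca
laura
sharon
cynthia
kathleen
amy
shirley
angela
heather
anna
brenda
pamela
nicole
ruth
katherine
samantha
christine
emma
catherine
debra
virginia
rachel
carolyn
janet
maria
olivia
heidi
diane
julie
victoria
kelly
christina
lauren
joan
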