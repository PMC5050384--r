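james
robert
john
michael
david
william
richard
joseph
thomas
charles
christopher
daniel
matthew
anthony
mark
donald
steven
paul
andrew
joshua
kenneth
kevin
brian
george
timothy
ronald
edward
jason
jeffrey
ryan
jacob
gary
nicholas
eric
jonathan
stephen
larry
justin
scott
brandon
benjamin
samuel
gregory
alexander
frank
patrick
raymond
jack
dennis
jerry
tyler
aaron
jose
adam
nathan
henry
douglas
zachary
peter
kyle
noah
ethan
jeremy
walter
christian
keith
roger
terry
austin
sean
gerald
carl
harold
dylan
arthur
lawrence
jordan
jesse
bryan
billy
bruce
gabriel
joe
logan
alan
juan
albert
willie
elijah
wayne
randy
vincent
mason
roy
ralph
bobby
russell
bradley
philip
eugene
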