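baban
baga
bago
baki
baku
balo
bane
bape
bapi
bapo
basa
bata
bati
batu
bavo
beba
beban
bebo
bemi
beni
bepan
besu
beta
bevi
bevu
bezan
bezu
biba
bibo
bike
bilo
bimu
bina
bipa
bipe
bira
biri
bise
bita
bitu
bivi
bizi
bodi
boge
boki
boli
boma
bomo
bone
bono
bori
boro
boso
bosu
bota
bote
bova
bubi
bubo
buda
budu
buke
bunu
bupe
bupu
buru
buso
buta
buva
buvu
buze
daba
daga
daka
daki
dako
dala
dana
dane
danu
daro
daru
dasan
dase
dasu
datu
davo
daze
dazi
dazo
debe
deben
debu
dedan
dede
deme
demi
demo
demu
desan
detu
devi
dide
diga
dige
digi
digo
diko
dilu
dime
dina
dino
diri
dise
divo
dode
dodo
doka
doke
doku
doli
dolo
domu
doni
dono
dope
dopo
dora
dore
dori
dosa
dosi
dosu
dote
dovi
dovo
doza
dozu
dube
dubu
dudi
dudo
dudu
duka
duki
dumo
duna
dupe
duro
duru
duso
duto
duvo
gaban
gabe
gabi
gadan
gaden
gadi
gagan
gage
gagi
gagu
gaku
ganan
ganen
ganu
gapi
garan
gase
gaso
gato
gatu
gazo
geba
gedan
gedo
gego
geke
geko
gelu
geman
gemu
gena
gene
gepo
gepu
geri
gero
gesa
gesan
gezi
gibi
gibu
gida
gido
gile
gilo
gilu
gimu
gini
gipi
gita
giti
givo
gize
gogo
goka
goko
golu
gona
goni
gopo
goro
goru
gosi
gosu
gota
gote
gova
govu
gube
gubi
gubu
guga
guge
gugu
guka
gume
gumi
gumu
gunu
guso
gusu
guta
kabi
kada
kadan
kade
kaki
kale
kali
kame
kana
kane
kanen
kapu
kara
karan
kari
kasa
kate
kati
kavan
kavi
kavu
kazi
kazo
keba
kebi
kebo
keda
kedo
keke
keken
kelan
kele
kelo
kemen
kene
kenen
keni
kete
kiba
kibe
kibi
kida
kigi
kika
kile
kipe
kiro
kisu
kitu
kivo
koge
kogo
koke
koli
koro
koso
kove
kubo
kuke
kuko
kuku
kumu
kuno
kupo
kuri
kuso
kuti
kuva
kuve
kuza
labo
lada
lade
lage
lagi
lalu
lanen
lani
lapan
laran
lare
laru
late
lava
lavu
lazan
lazi
lazo
leban
leben
lede
ledu
legan
leka
leki
lelo
lelu
leman
leme
lepa
lepo
leri
lesu
leta
letu
leve
levi
lezan
lezo
lezu
libu
lili
lima
line
lipa
lipu
lire
liro
liru
lito
live
livi
lobi
lodo
logu
loku
lomi
lomo
loni
lopo
lopu
loru
loso
lozo
lubi
ludu
lugi
lugo
lule
lumi
luno
lupe
lusi
lutu
luzo
mabo
mada
madi
magan
mage
maka
makan
malan
malo
mama
mamen
manu
mapi
mapo
mapu
maro
maru
masi
mati
mato
matu
mavan
maze
mazo
meban
mebe
meben
mebi
meda
mede
meden
medi
mega
mekan
meman
memi
mepa
mepe
meso
metan
metu
meve
mezan
mibi
miga
mila
mine
mipa
misi
miso
miva
mize
mobe
mobo
moda
modi
modu
moge
mogu
moke
moki
molu
momu
mone
mopa
mora
mori
moru
mote
movi
movu
moza
muba
mubo
mugi
mugu
muke
muki
muku
mulu
mumo
mumu
mune
muni
muno
mura
muru
muse
musi
muso
muta
mute
mutu
muvu
muzo
nabi
nadi
nage
naku
nale
nalen
namen
nami
namo
namu
nare
naro
nasa
nato
nava
nedan
nege
negu
neken
neki
neko
nela
neli
nemi
nene
nenen
neri
nero
nesa
nese
neso
nesu
neta
neto
nevan
nevo
nezo
niba
nide
nidu
niga
nigi
nigo
nika
nike
nila
nile
nilo
nine
ninu
nipe
nipo
niri
nive
nivo
niza
nole
nome
nomu
nopi
nopo
nora
noso
nota
notu
novu
noza
noze
nuga
nugi
nugu
nuka
numi
nuni
nura
nuro
nuso
nutu
nuvu
nuzi
paba
pada
padan
paga
page
pagi
paku
pala
palan
pamen
papa
papi
papu
pare
pari
paru
pasan
pase
paso
patan
pavan
pebo
peko
pela
pele
pema
pemu
pene
peni
peru
peta
peve
peza
pezi
pibo
pida
pidi
pidu
piki
piku
pimu
pinu
pipa
pipu
pire
pisa
pise
piso
pita
piva
pizu
pobu
pode
podi
poka
poko
pome
pona
pone
poni
popo
popu
poru
posi
posu
povi
pozu
pubi
puge
pugo
pugu
puka
puki
pula
puma
punu
puru
puso
pute
puvo
puzi
puzo
rabo
radan
raden
rado
radu
ragan
ragen
ragi
rako
ralen
ramo
ranan
rani
ranu
rape
rapo
rari
rasa
rata
ravan
ravu
raza
raze
razu
rede
rege
reke
reki
relu
rena
repu
rera
rere
reri
resa
reti
reto
reve
revi
revu
reze
rezo
riba
rida
ride
ridi
rige
rika
rima
rimu
rini
rino
ripa
ripi
rire
riru
risa
risi
riso
rita
riva
robu
rodi
rolo
romu
rone
ropa
ropi
roru
rosu
rove
rovo
rovu
rozo
rubu
rudi
rudo
rudu
rugu
ruke
rume
rune
rupe
rupo
rusi
ruti
ruto
saba
sabe
saben
sadan
sadi
sage
sago
saki
sale
sali
sama
samen
sanan
sanu
sapi
sara
saran
sasan
sasu
sate
savo
sazan
sazu
sebe
sedi
sega
segi
selo
sema
sepa
sesi
siba
sibi
sibo
sida
sidi
sigu
sili
silo
simi
sine
sipa
siru
siso
sisu
siva
sivo
siza
soba
sobo
sode
sogo
sola
soma
sonu
sore
sosa
sose
soso
soto
sovi
sozi
sulu
sumu
sunu
supa
supi
suri
suru
susi
suso
susu
suta
suto
suze
taben
tabi
taga
tago
takan
taku
talen
taru
tato
tatu
tavan
tavu
tazi
tebi
tegu
teki
teko
teme
tibu
tidu
tike
tiko
timo
tina
tine
tini
tipe
tira
tisi
tisu
tita
tivo
tizi
toga
tole
tomo
toni
tono
tonu
topi
topo
tori
tota
totu
tovo
tovu
tuba
tubi
tubo
tudo
tugi
tugu
tuku
tuni
tuno
tupe
ture
turo
tuvu
tuzi
vaban
vabi
vade
vagan
vakan
valo
vamen
vane
vapa
vapi
varan
vaso
vati
vava
vavi
vazi
vazu
vebo
veke
veli
vena
vepa
vepo
vepu
vere
vesa
veti
veto
veza
vezo
vida
vidu
viga
vike
viko
vile
vime
vimu
vise
visi
viti
vito
viva
vive
vobe
voko
voma
vomi
vope
vora
voru
vosa
vove
voza
vudi
vuka
vuko
vula
vule
vulo
vuna
vuri
vuso
zabu
zada
zade
zage
zagu
zala
zalen
zamu
zana
zanan
zane
zanen
zanu
zape
zare
zasan
zasu
zatu
zeda
zega
zelo
zelu
zeme
zemi
zemu
zeni
zepa
zepe
zepo
zera
zeri
zesa
zeso
zeto
zetu
zeva
zevu
ziba
zibo
zige
ziko
ziku
zila
zile
zino
zisi
ziso
zita
zite
zitu
ziva
zizu
zobo
zogo
zoki
zoku
zomo
zoni
zosa
zose
zoti
zuba
zube
zuge
zuki
zuku
zule
zuli
zuma
zume
zuno
zupe
zupo
zupu
zuso
zuta
zuve
zuvo
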